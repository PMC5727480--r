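test_that("Hedman posterior handles the degenerate and one-outgroup cases", {
  h0 <- hedman_node_age(290, node_min_age = 285, t_max = 285)
  expect_equal(h0$mean, 285)
  expect_equal(sum(h0$prob), 1)

  # single outgroup at t_max: uniform on [min, t_max], mean at the midpoint
  h1 <- hedman_node_age(300, node_min_age = 280, t_max = 300)
  expect_equal(h1$mean, 290, tolerance = 1e-6)
  expect_equal(sum(h1$prob), 1)
  expect_lt(diff(range(h1$prob)), 1e-12)   # flat density

  expect_error(hedman_node_age(300, node_min_age = 300, t_max = 290),
               "younger")
  expect_error(hedman_node_age(300, 280, 300, grid_resolution = 10),
               "grid_resolution")
})

test_that("Hedman grid recursion matches forward Monte Carlo sampling", {
  ogs <- c(310, 300, 295)  # old to young
  h <- hedman_node_age(ogs, node_min_age = 280, t_max = 320,
                       grid_resolution = 2000)
  set.seed(400)
  n <- 200000
  d <- runif(n, 310, 320)
  d <- runif(n, 300, d)
  d <- runif(n, 295, d)
  node <- runif(n, 280, d)
  expect_equal(h$mean, mean(node), tolerance = 0.05)
  expect_equal(stats::quantile(node, 0.5)[[1]],
               h$ages[which(cumsum(h$prob) >= 0.5)[1]], tolerance = 0.2)
})

test_that("doubling the grid resolution barely moves the mean", {
  a <- hedman_node_age(c(305, 300), 285, 315, grid_resolution = 1000)
  b <- hedman_node_age(c(305, 300), 285, 315, grid_resolution = 2000)
  expect_lt(abs(a$mean - b$mean), 0.1)
})

test_that("posterior mean is monotone in t_max", {
  means <- vapply(seq(300, 325, by = 5), function(tm)
    hedman_node_age(c(300, 298), 285, tm)$mean, numeric(1))
  expect_true(all(diff(means) >= -1e-9))
})

test_that("calibrated trees are stratigraphically consistent", {
  set.seed(50)
  tree <- simulate_tree(12, seed = 8)
  taxa <- simulate_ranges_and_diets(
    tree, matrix(rnorm(12), 12, 1, dimnames = list(tree$tip.label, NULL)))
  og <- data.frame(name = c("Og1", "Og2"), age = c(308, 315))
  cal <- calibrate_tree(tree, taxa, og, root_max = 325, n_draws = 500,
                        seed = 3)
  ntip <- 12
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    if (ch > ntip)
      expect_true(all(cal$draws[, p - ntip] >= cal$draws[, ch - ntip] - 1e-9))
  }
  expect_true(all(cal$draws[, 1] <= 325 + 1e-9))
  expect_true(cal$tree$root.time >= max(taxa$fad))
  expect_true(all(cal$tree$edge.length >= -1e-9))
  # determinism
  cal2 <- calibrate_tree(tree, taxa, og, root_max = 325, n_draws = 500,
                         seed = 3)
  expect_identical(cal$draws, cal2$draws)
})

test_that("degenerate calibration collapses to the shared age", {
  tr <- ape::read.tree(text = "((A,B),C);")
  taxa <- taxon_records(c("A", "B", "C"), fad = c(300, 300, 300),
                        lad = c(295, 295, 295))
  cal <- calibrate_tree(tr, taxa, data.frame(name = "O", age = 300),
                        root_max = 300, n_draws = 50, seed = 1)
  expect_true(all(abs(cal$draws - 300) < 1e-9))
  expect_equal(sum(cal$tree$edge.length), 0)
})

test_that("inconsistent user outgroups are rejected by name", {
  tr <- ape::read.tree(text = "((A,B),C);")
  taxa <- taxon_records(c("A", "B", "C"), c(300, 299, 298),
                        c(295, 295, 295))
  expect_error(
    calibrate_tree(tr, taxa,
                   data.frame(name = c("Near", "Far"), age = c(310, 305)),
                   root_max = 325),
    "Far")
})

test_that("bin construction matches the published schemes", {
  five <- make_bins("five")
  expect_equal(nrow(five), 5)
  expect_equal(five$name[1], "Asselian-Sakmarian")
  expect_equal(five$name, c("Asselian-Sakmarian", "Artinskian", "Kungurian",
                            "Guadalupian", "Lopingian"))
  stages <- make_bins("stages")
  expect_equal(nrow(stages), 10)
  expect_equal(stages$name[1], "Gzhelian")
  expect_equal(stages$name[10], "Changhsingian")
  for (b in list(five, stages)) {
    expect_true(all(b$start > b$end))
    expect_true(all(diff(b$start) < 0))           # ordered old -> young
    expect_true(all(b$end[-nrow(b)] >= b$start[-1] - 1e-9))  # no overlap
  }
  expect_equal(five$start[3], 283.5)   # Kungurian bounds
  expect_equal(five$end[3], 273.01)
  expect_error(make_bins(data.frame(name = "x", start = 1, end = 2)),
               "start > end")
})

test_that("dated node ages are recoverable from branch lengths", {
  set.seed(12)
  tree <- simulate_tree(8, seed = 2)
  ages <- node_ages(tree)
  spans <- attr(tree, "lineage_spans")
  expect_equal(unname(ages[seq_len(8)]), unname(spans[, "end"]),
               tolerance = 1e-9)
  expect_equal(max(ages), tree$root.time)
})
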