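test_that("bin assignment follows overlap semantics with boundary rule", {
  bins <- make_bins("five")
  taxa <- taxon_records(
    c("in_kungurian", "older", "range_through", "boundary_point"),
    fad = c(285, 300, 290, 283.5),
    lad = c(280, 295, 260, 283.5))
  mem <- suppressWarnings(assign_bins(taxa, bins))
  expect_true("in_kungurian" %in% mem$Kungurian)
  expect_false("older" %in% mem$Kungurian)
  # range-through taxon appears in every overlapped bin
  expect_true(all(vapply(mem[c("Artinskian", "Kungurian", "Guadalupian")],
                         function(x) "range_through" %in% x, logical(1))))
  # point occurrence on the Artinskian/Kungurian boundary -> older bin
  expect_true("boundary_point" %in% mem$Artinskian)
  expect_false("boundary_point" %in% mem$Kungurian)
  expect_warning(assign_bins(taxon_records("new", 10, 5), bins), "outside")
})

test_that("sum of variances and ranges match hand examples", {
  s <- matrix(c(0, 2, 4), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(sum_of_variances(s), 4)
  expect_equal(sum_of_ranges(s), 4)
  expect_equal(sum_of_ranges(s[1, , drop = FALSE]), 0)
  expect_true(is.na(sum_of_variances(s[1, , drop = FALSE])))
  same <- matrix(1, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_equal(sum_of_variances(same), 0)

  set.seed(3)
  m <- matrix(rnorm(18), 6, 3, dimnames = list(paste0("t", 1:6), NULL))
  expect_equal(sum_of_variances(m, axes = 1:2),
               sum_of_variances(m, axes = 1) + sum_of_variances(m, axes = 2))
  # adding a taxon never decreases the sum of ranges
  expect_gte(sum_of_ranges(m), sum_of_ranges(m[-1, ]))
  # brute-force recomputation of SoV
  expect_equal(sum_of_variances(m),
               sum(vapply(1:3, function(j) {
                 x <- m[, j]
                 sum((x - mean(x))^2) / (length(x) - 1)
               }, numeric(1))))
})

test_that("bootstrap CIs behave like percentile intervals", {
  set.seed(11)
  s <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("t", 1:20), NULL))
  b <- bootstrap_disparity(s, metric = "sov", n_boot = 300, seed = 4)
  expect_lt(b$ci[1], b$estimate)
  expect_gt(b$ci[2], b$estimate)
  b2 <- bootstrap_disparity(s, metric = "sov", n_boot = 300, seed = 4)
  expect_identical(b$ci, b2$ci)
  zero <- matrix(0, 5, 2, dimnames = list(paste0("t", 1:5), NULL))
  bz <- bootstrap_disparity(zero, metric = "sor", n_boot = 100, seed = 1)
  expect_equal(bz$ci, c(0, 0))
  expect_error(bootstrap_disparity(s, n_boot = 10), "n_boot")

  # percentile CI covers the point estimate in the vast majority of draws
  hits <- 0
  for (r in 1:100) {
    s <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("t", 1:12), NULL))
    b <- bootstrap_disparity(s, metric = "sov", n_boot = 200)
    if (b$ci[1] <= b$estimate && b$estimate <= b$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("CGS matches closed forms on equal bins", {
  bins <- equal_bins(3)
  expect_equal(cgs(c(1, 1, 1), bins)$cgs, 0.5)
  expect_equal(cgs(c(1, 1, 1), bins)$null, 0.5)
  expect_equal(cgs(c(1, 0, 0), bins)$cgs, 1 / 6)
  expect_equal(cgs(c(0, 0, 1), bins)$cgs, 5 / 6)
  expect_equal(cgs(c(2, 5, 2), bins)$cgs, 0.5)  # symmetric profile
  # reversed profile mirrors around 0.5
  set.seed(5)
  v <- runif(5)
  b5 <- equal_bins(5)
  expect_equal(cgs(rev(v), b5)$cgs, 1 - cgs(v, b5)$cgs, tolerance = 1e-12)
  expect_error(cgs(c(1, 1), equal_bins(2)), "3 occupied")
  expect_error(cgs(c(0, 0, 0), bins), "all-zero")
})

test_that("unequal bins shift the flat-profile null away from 0.5", {
  bins <- time_bins(c("long", "short1", "short2"),
                    c(300, 280, 275), c(280, 275, 270))
  res <- cgs(c(1, 1, 1), bins)
  expect_equal(res$cgs, res$null)
  expect_false(isTRUE(all.equal(res$null, 0.5)))
})

test_that("CGS bootstrap p-value is deterministic and sane", {
  set.seed(8)
  bins <- equal_bins(5)
  bs <- flat_bin_scores(bins, n_per_bin = 10)
  a <- cgs_bootstrap(bs, bins, "sov", n_boot = 199, seed = 2)
  b <- cgs_bootstrap(bs, bins, "sov", n_boot = 199, seed = 2)
  expect_identical(a$p_value, b$p_value)
  expect_true(a$p_value >= 0 && a$p_value <= 1)
  # strongly bottom-heavy profile: low CGS
  heavy <- bs
  heavy[[4]] <- heavy[[4]] * 0.05
  heavy[[5]] <- heavy[[5]] * 0.05
  res <- cgs_bootstrap(heavy, bins, "sov", n_boot = 199, seed = 3)
  expect_lt(res$cgs, 0.5)
})

test_that("diet counts form a faithful contingency table", {
  bins <- make_bins("five")
  taxa <- taxon_records(
    c("c1", "c2", "o1", "h1"),
    fad = c(295, 287, 280, 278), lad = c(291, 284, 276, 274),
    diet = c("carnivore", "carnivore", "omnivore", "herbivore"))
  dc <- diet_counts(taxa, bins)
  expect_equal(dc$carnivore[dc$bin == "Asselian-Sakmarian"], 1)
  expect_equal(dc$carnivore[dc$bin == "Artinskian"], 1)
  expect_equal(dc$omnivore[dc$bin == "Kungurian"], 1)
  expect_equal(dc$herbivore[dc$bin == "Kungurian"], 1)
  # row sums match bin membership sizes
  mem <- suppressWarnings(assign_bins(taxa, bins))
  expect_equal(dc$total, unname(lengths(mem)))
  expect_equal(rowSums(dc[, c("carnivore", "omnivore", "herbivore")]),
               dc$total, ignore_attr = TRUE)
  # all-carnivore data leaves the other columns empty
  allc <- taxon_records(c("x", "y"), c(295, 285), c(290, 280),
                        c("carnivore", "carnivore"))
  dca <- diet_counts(allc, bins)
  expect_true(all(dca$omnivore == 0) && all(dca$herbivore == 0))
})

test_that("convex hull areas and overlaps match constructed geometry", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rownames(sq) <- paste0("s", 1:4)
  inner <- rbind(c(0.25, 0.25), c(0.75, 0.25), c(0.75, 0.75), c(0.25, 0.75))
  rownames(inner) <- paste0("i", 1:4)
  far <- rbind(c(5, 5), c(6, 5), c(5.5, 6))
  rownames(far) <- paste0("f", 1:3)
  scores <- rbind(sq, inner, far)
  groups <- setNames(rep(c("sq", "inner", "far"), c(4, 4, 3)),
                     rownames(scores))
  res <- convex_hull_areas(scores, groups)
  expect_equal(res$areas[["sq"]], 1)
  expect_equal(res$areas[["inner"]], 0.25)
  expect_equal(res$overlap["sq", "far"], 0)       # disjoint
  expect_equal(res$overlap["sq", "inner"], 0.25)  # nested: inner hull area
  # degenerate group: fewer than 3 points
  g2 <- setNames(c("a", "a", "b", "b", "b"), paste0("p", 1:5))
  s2 <- cbind(c(0, 1, 3, 4, 3.5), c(0, 0, 0, 0, 1))
  rownames(s2) <- names(g2)
  r2 <- convex_hull_areas(s2, g2)
  expect_equal(r2$areas[["a"]], 0)
})
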