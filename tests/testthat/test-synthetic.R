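test_that("the generator is deterministic and shape-faithful", {
  a <- simulate_dataset(n_taxa = 12, seed = 77)
  b <- simulate_dataset(n_taxa = 12, seed = 77)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$discrete$states, b$discrete$states)
  expect_identical(unclass(a$continuous), unclass(b$continuous))
  expect_identical(a$taxa, b$taxa)
  expect_equal(length(a$taxa$name), 12)
  expect_equal(a$discrete$nchar, 75)
  expect_equal(ncol(a$continuous), 31)
  c2 <- simulate_dataset(n_taxa = 12, seed = 78)
  expect_false(identical(ape::write.tree(a$tree), ape::write.tree(c2$tree)))
})

test_that("pure-birth clades are ultrametric; extinct tips are retained", {
  t0 <- simulate_tree(10, birth_rate = 0.25, death_rate = 0,
                      origin_age = 12, seed = 3)
  expect_true(all(abs(node_ages(t0)[1:10]) < 1e-9))
  t1 <- simulate_tree(15, seed = 9)
  expect_true(any(node_ages(t1)[1:15] > 1e-6))   # extinct tips above 0 Ma
  expect_true(all(t1$edge.length > 0))
  expect_equal(max(node_ages(t1)), t1$root.time)
})

test_that("planted missing and polymorphic fractions are realised", {
  ds <- simulate_dataset(n_taxa = 25, missing_frac = 0.3, poly_frac = 0.05,
                         seed = 41)
  n_cells <- 25 * 75
  mf <- missing_fraction(ds$discrete)
  ci <- qbinom(c(0.0005, 0.9995), n_cells, 0.3) / n_cells
  expect_gte(mf, ci[1]); expect_lte(mf, ci[2])
  pf <- mean(vapply(ds$discrete$states, function(s) length(s) > 1,
                    logical(1)))
  ci_p <- qbinom(c(0.0005, 0.9995), n_cells, 0.05) / n_cells
  expect_gte(pf, ci_p[1]); expect_lte(pf, ci_p[2])
  expect_true(all(unlist(ds$discrete$states)[
    !is.na(unlist(ds$discrete$states))] < 2))
})

test_that("zero-rate traits are constant; BM covariance tracks the tree", {
  tree <- simulate_tree(10, seed = 5)
  cc <- simulate_continuous(tree, sigma2 = 1e-12, n_chars = 3, seed = 2)
  expect_lt(diff(range(unclass(cc$matrix))), 1e-4)

  # tip-pair covariance ~ sigma2 x shared path length (many characters);
  # pick the pair with the deepest shared history and allow 4 SE of
  # sampling noise: SE^2 = (C_ii C_jj + C_ij^2) / n_chars
  cc2 <- simulate_continuous(tree, sigma2 = 1, n_chars = 500, seed = 3)
  lt <- cc2$log_tips
  C <- ape::vcv(tree)[rownames(lt), rownames(lt)]
  off <- C; diag(off) <- 0
  ij <- which(off == max(off), arr.ind = TRUE)[1, ]
  i <- ij[1]; j <- ij[2]
  emp <- cov(lt[i, ], lt[j, ])
  se <- sqrt((C[i, i] * C[j, j] + C[i, j]^2) / ncol(lt))
  expect_lt(abs(emp - C[i, j]), 4 * se)
})

test_that("sampled ranges sit inside true durations; diets are planted", {
  ds <- simulate_dataset(n_taxa = 20, seed = 13)
  spans <- ds$truth$lineage_spans
  expect_true(all(ds$taxa$fad <= spans[ds$taxa$name, "start"] + 1e-9))
  expect_true(all(ds$taxa$lad >= spans[ds$taxa$name, "end"] - 1e-9))
  expect_true(all(ds$taxa$fad >= ds$taxa$lad))
  # diets are a deterministic function of trait 1
  x <- ds$truth$log_tips[ds$taxa$name, 1]
  q <- quantile(x, c(0.5, 0.8))
  expected <- ifelse(x < q[1], "carnivore",
                     ifelse(x < q[2], "omnivore", "herbivore"))
  expect_equal(ds$taxa$diet, unname(expected))
  # a planted late-herbivore schedule is recovered exactly by diet_counts
  taxa <- taxon_records(c("c1", "c2", "h1", "h2"),
                        fad = c(298, 292, 282, 280),
                        lad = c(296, 290, 280, 276),
                        diet = c("carnivore", "carnivore", "herbivore",
                                 "herbivore"))
  dc <- diet_counts(taxa, make_bins("five"))
  first_herb <- dc$bin[which(dc$herbivore > 0)[1]]
  expect_equal(first_herb, "Kungurian")
})

test_that("high preservation rates recover nearly the true duration", {
  tree <- simulate_tree(10, seed = 23)
  tr_long <- simulate_ranges_and_diets(
    tree, matrix(rnorm(10), 10, 1, dimnames = list(tree$tip.label, NULL)),
    preservation_rate = 200, seed = 2)
  spans <- attr(tree, "lineage_spans")
  expect_equal(tr_long$fad, unname(spans[tr_long$name, "start"]),
               tolerance = 0.05)
  expect_equal(tr_long$lad, unname(spans[tr_long$name, "end"]),
               tolerance = 0.05)
})

test_that("BM rate is recoverable from contrast variance", {
  set.seed(29)
  tree <- simulate_tree(40, seed = 17)
  sig_hat <- replicate(40, {
    x <- phytools::fastBM(tree, sig2 = 0.5)
    mean(pic_contrasts(tree, x)^2)
  })
  expect_lt(abs(median(sig_hat) - 0.5) / 0.5, 0.15)
})
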