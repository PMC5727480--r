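test_that("log-ratio transform behaves like a log", {
  m <- continuous_matrix(rbind(A = c(1.0, 2.0), B = c(0.5, 8.0)))
  lr <- logratio_transform(m)
  expect_equal(lr["A", 1], 0, ignore_attr = TRUE)
  expect_equal(lr["B", 2], log(8), ignore_attr = TRUE)
  # log additivity: log(a*b) = log(a) + log(b)
  ab <- continuous_matrix(rbind(X = c(2 * 3, 2, 3)))
  l <- logratio_transform(ab)
  expect_equal(l[1, 1], l[1, 2] + l[1, 3])
  expect_error(logratio_transform(
    structure(rbind(A = -0.2), class = class(m))), "positive")
})

test_that("mean imputation preserves character means", {
  m <- rbind(A = c(1, 5), B = c(NA, 6), C = c(3, 7))
  out <- mean_impute(m)
  expect_equal(out["B", 1], 2, ignore_attr = TRUE)
  expect_equal(colMeans(out)[1], mean(c(1, 3)), ignore_attr = TRUE)
  complete <- rbind(A = c(1, 2), B = c(3, 4))
  expect_identical(mean_impute(complete), complete)
  expect_error(mean_impute(rbind(A = NA_real_, B = NA_real_)), "impute")
})

test_that("PCA conserves total variance and handles collinear data", {
  set.seed(7)
  for (r in 1:5) {
    m <- matrix(rnorm(30 * 31), 30, 31,
                dimnames = list(paste0("t", 1:30), NULL))
    p <- pca_ordination(m)
    expect_equal(sum(p$axis_variances), sum(apply(m, 2, var)),
                 tolerance = 1e-10)
    expect_true(all(diff(p$axis_variances) <= 1e-9))
    expect_true(all(abs(colMeans(p$scores)) < 1e-9))
    # inter-taxon distances survive any axis sign flip
    d1 <- dist(p$scores)
    flip <- p$scores %*% diag(sample(c(-1, 1), ncol(p$scores), TRUE))
    expect_equal(as.vector(dist(flip)), as.vector(d1), tolerance = 1e-9)
  }
  line <- cbind(1:5, 2 * (1:5))
  rownames(line) <- paste0("t", 1:5)
  pl <- pca_ordination(line)
  expect_equal(pl$n_positive, 1)
  expect_lt(pl$axis_variances[2], 1e-12)
  expect_error(pca_ordination(line[1, , drop = FALSE]), "2 taxa")
})

test_that("MORD matches the hand-computed example and edge cases", {
  m <- discrete_matrix(rbind(X = c("0", "1", "?", "0"),
                             Y = c("1", "1", "0", "{01}")))
  d <- mord(m)
  expect_equal(d$distances["X", "Y"], 1 / 3)
  expect_equal(d$comparable["X", "Y"], 3)

  ident <- discrete_matrix(rbind(A = c("0", "1"), B = c("0", "1")))
  expect_equal(mord(ident)$distances["A", "B"], 0)

  anti <- discrete_matrix(rbind(A = c("0", "0", "0"), B = c("1", "1", "1")))
  expect_equal(mord(anti)$distances["A", "B"], 1)

  # ordered characters rescale by observed range
  om <- discrete_matrix(rbind(A = c("0"), B = c("2"), C = c("4")),
                        ordering = "ordered")
  d2 <- mord(om)$distances
  expect_equal(d2["A", "B"], 0.5)
  expect_equal(d2["A", "C"], 1)
})

test_that("MORD agrees with the per-pair oracle under heavy missing data", {
  set.seed(19)
  for (r in 1:25) {
    inst <- random_discrete_instance(sample(5:8, 1), sample(5:12, 1),
                                     p_missing = 0.3, p_poly = 0.1)
    m <- inst$matrix
    d <- suppressWarnings(mord(m, incomparable = "na"))
    for (i in 1:(length(m$taxa) - 1)) for (k in (i + 1):length(m$taxa)) {
      expect_equal(d$distances[i, k], oracle_mord_pair(m, i, k),
                   info = paste("case", r, "pair", i, k))
    }
  }
})

test_that("MORD is equivariant to taxon and character permutations", {
  set.seed(23)
  inst <- random_discrete_instance(6, 10, p_missing = 0.2)
  m <- inst$matrix
  d <- suppressWarnings(mord(m, incomparable = "na"))$distances
  pt <- sample(length(m$taxa))
  pc <- sample(m$nchar)
  m2 <- discrete_matrix(m$states[pt, pc, drop = FALSE],
                        taxa = m$taxa[pt], ordering = m$ordering[pc])
  d2 <- suppressWarnings(mord(m2, incomparable = "na"))$distances
  expect_equal(d2[m$taxa, m$taxa], d, tolerance = 1e-12)
})

test_that("incomparable pairs are flagged and filled by policy", {
  m <- discrete_matrix(rbind(A = c("0", "?"), B = c("?", "1"),
                             C = c("1", "0")))
  expect_warning(d <- mord(m), "incomparable")
  expect_equal(nrow(d$incomparable_pairs), 1)
  expect_equal(d$distances["A", "B"], max(d$distances["A", "C"],
                                          d$distances["B", "C"]))
  dna <- mord(m, incomparable = "na")
  expect_true(is.na(dna$distances["A", "B"]))
})

test_that("PCoA reproduces the collinear worked example", {
  D <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- pcoa_ordination(D)
  expect_equal(p$n_positive, 1)
  expect_equal(p$eigenvalues[1], 2, tolerance = 1e-10)
  expect_equal(sort(p$scores[, 1]), c(-1, 0, 1), tolerance = 1e-10,
               ignore_attr = TRUE)
  zero <- matrix(0, 3, 3)
  pz <- pcoa_ordination(zero)
  expect_equal(pz$n_positive, 0)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA on Euclidean PCA-score distances recovers PCA variances", {
  set.seed(31)
  m <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(paste0("t", 1:20), NULL))
  p <- pca_ordination(m)
  q <- pcoa_ordination(as.matrix(dist(p$scores)))
  k <- p$n_positive
  expect_equal(q$axis_variances[seq_len(k)], unname(p$axis_variances[seq_len(k)]),
               tolerance = 1e-8)
  # distances among PCoA scores reproduce the (Euclidean) input distances
  expect_equal(as.vector(dist(q$scores)), as.vector(dist(p$scores)),
               tolerance = 1e-8)
  # cross-check against the standard cmdscale implementation
  cs <- stats::cmdscale(dist(p$scores), k = k, eig = TRUE)
  expect_equal(q$eigenvalues[seq_len(k)], cs$eig[seq_len(k)],
               tolerance = 1e-8)
})
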