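test_that("Fitch length matches hand examples", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_length(tr, discrete_matrix(
    rbind(A = "0", B = "0", C = "1", D = "1"))), 1)
  expect_equal(fitch_length(tr, discrete_matrix(
    rbind(A = "0", B = "1", C = "0", D = "1"))), 2)
  expect_equal(fitch_length(tr, discrete_matrix(
    rbind(A = "?", B = "?", C = "?", D = "?"))), 0)
  expect_error(fitch_length(tr, discrete_matrix(
    rbind(A = "0", B = "0", C = "1"))), "absent")
})

test_that("Fitch length equals the exhaustive brute-force minimum", {
  set.seed(101)
  for (r in 1:60) {
    inst <- random_discrete_instance(sample(4:6, 1), sample(2:4, 1))
    expect_equal(fitch_length(inst$tree, inst$matrix),
                 oracle_fitch(inst$tree, inst$matrix),
                 info = paste("case", r))
  }
})

test_that("Fitch length agrees with phangorn on unambiguous matrices", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  for (r in 1:10) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n, br = NULL)
    cells <- matrix(as.character(sample(0:2, n * 15, TRUE)), n, 15,
                    dimnames = list(tr$tip.label, NULL))
    pd <- phangorn::as.phyDat(cells, type = "USER",
                              levels = c("0", "1", "2"))
    expect_equal(fitch_length(tr, discrete_matrix(cells)),
                 phangorn::parsimony(tr, pd))
  }
})

test_that("tree length is invariant to rerooting and all-missing taxa", {
  set.seed(55)
  inst <- random_discrete_instance(7, 10)
  len <- fitch_length(inst$tree, inst$matrix)
  for (tip in inst$tree$tip.label) {
    rt <- ape::root(ape::unroot(inst$tree), outgroup = tip,
                    resolve.root = TRUE)
    expect_equal(fitch_length(rt, inst$matrix), len)
  }
  # graft an all-missing taxon on any edge: length unchanged
  states <- rbind(inst$matrix$states,
                  matrix(list(NA_integer_), 1, inst$matrix$nchar))
  m2 <- discrete_matrix(states, taxa = c(inst$matrix$taxa, "blank"))
  for (k in c(1, 3, nrow(inst$tree$edge))) {
    t2 <- dispartime:::graft_on_edge(inst$tree, "blank", k)
    expect_equal(fitch_length(t2, m2), len)
  }
})

test_that("Farris length matches hand examples and brute force", {
  tr <- ape::read.tree(text = "((A,B),C);")
  expect_equal(farris_length(tr, continuous_matrix(
    rbind(A = 0.1, B = 0.2, C = 0.5))), 0.4)
  expect_equal(farris_length(tr, continuous_matrix(
    rbind(A = 0.3, B = 0.3, C = 0.3))), 0)
  two <- ape::read.tree(text = "(A,B);")
  expect_equal(farris_length(two, continuous_matrix(
    rbind(A = 0.25, B = 0.75))), 0.5)

  set.seed(202)
  for (r in 1:40) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, br = NULL)
    vals <- matrix(round(exp(rnorm(n * 2)), 2), n, 2,
                   dimnames = list(tr$tip.label, NULL))
    vals[runif(length(vals)) < 0.15] <- NA
    ok <- apply(vals, 2, function(x) any(!is.na(x)))
    vals <- vals[, ok, drop = FALSE]
    if (ncol(vals) == 0) next
    m <- continuous_matrix(vals)
    expect_equal(farris_length(tr, m), oracle_farris(tr, m),
                 tolerance = 1e-9, info = paste("case", r))
  }
})

test_that("fit indices match the worked example and identities", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  f <- fit_indices(tr, discrete_matrix(
    rbind(A = "0", B = "1", C = "0", D = "1")))
  expect_equal(f$per_char$s, 2)
  expect_equal(f$per_char$m, 1)
  expect_equal(f$per_char$g, 2)
  expect_equal(f$CI, 0.5)
  expect_equal(f$RI, 0)

  # perfectly congruent characters: CI = 1, HI = 0, RI = 1
  set.seed(9)
  tree <- ape::rtree(8, br = NULL)
  clean <- clean_matrix_for(tree)
  fc <- fit_indices(tree, clean)
  expect_equal(fc$CI, 1)
  expect_equal(fc$HI, 0)
  expect_equal(fc$RI, 1)

  # exact ensemble identities on random instances
  for (r in 1:10) {
    inst <- random_discrete_instance(6, 8)
    f <- fit_indices(inst$tree, inst$matrix)
    expect_true(all(f$per_char$m <= f$per_char$s + 1e-9))
    expect_true(all(f$per_char$s <= f$per_char$g + 1e-9))
    expect_equal(f$CI * sum(f$per_char$s), sum(f$per_char$m))
    expect_equal(f$HI + f$CI, 1)
  }

  # constant-only matrix: RI undefined and flagged
  const <- discrete_matrix(rbind(A = "0", B = "0", C = "0", D = "0"))
  fk <- fit_indices(tr, const)
  expect_false(fk$ri_defined)
  expect_true(is.na(fk$RI))
})

test_that("polymorphism counts toward its most favourable state in g", {
  # A={0}, B={1}, C={0,1}, D={2}: best single state covers 2 of 4 scored
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- discrete_matrix(rbind(A = "0", B = "1", C = "{01}", D = "2"))
  f <- fit_indices(tr, m)
  expect_equal(f$per_char$g, 4 - 2)
  # polymorphic-only states never force minimum steps
  m2 <- discrete_matrix(rbind(A = "0", B = "{01}", C = "0", D = "0"))
  f2 <- fit_indices(tr, m2)
  expect_equal(f2$per_char$m, 0)
  expect_equal(f2$per_char$s, 0)
})
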