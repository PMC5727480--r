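# Independent brute-force oracles and small fixture builders. These share no
# code with the implementation paths they check.

# All rooted binary shapes are reachable from ape::rtree; random state sets
# include missing and polymorphic cells.
random_discrete_instance <- function(n_tips, n_chars, n_states = 3,
                                     p_missing = 0.15, p_poly = 0.15) {
  tree <- ape::rtree(n_tips, br = NULL)
  states <- matrix(vector("list", n_tips * n_chars), n_tips, n_chars)
  for (i in seq_len(n_tips)) for (j in seq_len(n_chars)) {
    u <- runif(1)
    if (u < p_missing) states[[i, j]] <- NA_integer_
    else if (u < p_missing + p_poly)
      states[[i, j]] <- sort(sample(0:(n_states - 1), 2))
    else states[[i, j]] <- sample(0:(n_states - 1), 1)
  }
  list(tree = tree,
       matrix = discrete_matrix(states, taxa = tree$tip.label))
}

# Exhaustive Fitch: minimise total changes over every assignment of single
# states to internal nodes; a tip contributes 0 when its parent's state is
# in its set (the tip realises that state), else 1. Missing = universal set.
oracle_fitch <- function(tree, m) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  total <- 0
  all_states_mat <- m$states[match(tree$tip.label, m$taxa), , drop = FALSE]
  for (j in seq_len(m$nchar)) {
    sets <- all_states_mat[, j]
    obs <- sort(unique(unlist(sets[!vapply(sets, function(x)
      length(x) == 1 && is.na(x[1]), logical(1))])))
    if (length(obs) == 0) next
    sets <- lapply(sets, function(x)
      if (length(x) == 1 && is.na(x[1])) obs else x)
    combos <- as.matrix(expand.grid(rep(list(obs), nnode)))
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      assign <- combos[r, ]
      cost <- 0
      for (k in seq_len(nrow(tree$edge))) {
        u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
        su <- assign[u - ntip]
        cost <- cost + if (v <= ntip) as.numeric(!su %in% sets[[v]])
                       else as.numeric(su != assign[v - ntip])
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  unname(total)
}

# Exhaustive Wagner/Farris: internal values restricted to the set of tip
# values (an optimal solution always exists there for Manhattan cost).
oracle_farris <- function(tree, m) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  vals_mat <- unclass(m)[match(tree$tip.label, rownames(m)), , drop = FALSE]
  total <- 0
  for (j in seq_len(ncol(vals_mat))) {
    x <- vals_mat[, j]
    grid <- sort(unique(x[!is.na(x)]))
    if (length(grid) == 0) next
    combos <- as.matrix(expand.grid(rep(list(grid), nnode)))
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      assign <- combos[r, ]
      cost <- 0
      for (k in seq_len(nrow(tree$edge))) {
        u <- tree$edge[k, 1]; v <- tree$edge[k, 2]
        vu <- assign[u - ntip]
        vv <- if (v <= ntip) x[v] else assign[v - ntip]
        if (!is.na(vv)) cost <- cost + abs(vu - vv)
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  unname(total)
}

# MORD from the written definition, one explicit pair at a time.
oracle_mord_pair <- function(m, i, k) {
  num <- 0; den <- 0
  for (j in seq_len(m$nchar)) {
    a <- m$states[[i, j]]; b <- m$states[[k, j]]
    a_missing <- length(a) == 1 && is.na(a[1])
    b_missing <- length(b) == 1 && is.na(b[1])
    if (a_missing || b_missing) next
    if (m$ordering[j] == "ordered") {
      st <- unlist(m$states[, j]); st <- st[!is.na(st)]
      rng <- if (length(st) >= 2) max(max(st) - min(st), 1) else 1
      num <- num + min(abs(outer(a, b, "-"))) / rng
    } else {
      num <- num + as.numeric(!any(a %in% b))
    }
    den <- den + 1
  }
  if (den == 0) NA_real_ else num / den
}

# A matrix in which every non-trivial clade of `tree` is supported by
# `per_clade` binary characters (no homoplasy).
clean_matrix_for <- function(tree, per_clade = 2) {
  ntip <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  cols <- list()
  for (i in seq_along(pp)) {
    sz <- length(pp[[i]])
    if (sz %in% c(1, ntip)) next
    col <- rep("0", ntip); col[pp[[i]]] <- "1"
    for (r in seq_len(per_clade)) cols[[length(cols) + 1]] <- col
  }
  cells <- do.call(cbind, cols)
  rownames(cells) <- tree$tip.label
  discrete_matrix(cells)
}

# Five equal-length 10-Myr bins, 300-250 Ma.
equal_bins <- function(n = 5, start = 300, width = 10) {
  time_bins(paste0("b", seq_len(n)),
            start - width * (seq_len(n) - 1),
            start - width * seq_len(n))
}

# Per-bin iid normal score sets (no temporal signal): the symmetric null
# for CGS testing.
flat_bin_scores <- function(bins, n_per_bin = 8, n_axes = 3) {
  out <- lapply(seq_len(nrow(bins)), function(i) {
    m <- matrix(rnorm(n_per_bin * n_axes), n_per_bin, n_axes)
    rownames(m) <- paste0("b", i, "_x", seq_len(n_per_bin))
    m
  })
  names(out) <- bins$name
  structure(out, class = "bin_scores")
}
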