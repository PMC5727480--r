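# Heuristic parsimony search: random-addition starting trees plus NNI/SPR
# branch swapping, on rooted binary phylo objects (tree length is invariant
# to root placement, so the search explores unrooted topology space).

# --- tree surgery -----------------------------------------------------------

# Graft `subtree` (a phylo, or a single tip label) onto edge `edge_idx` of
# `backbone`, splitting that edge with a new attachment node. Node numbering
# is kept valid for ape (tips first, root = Ntip + 1).
graft_on_edge <- function(backbone, subtree, edge_idx) {
  nb <- ape::Ntip(backbone); mb <- backbone$Nnode
  single <- is.character(subtree)
  ns <- if (single) 1L else ape::Ntip(subtree)
  ms <- if (single) 0L else subtree$Nnode
  N <- nb + ns
  E <- backbone$edge
  E[E > nb] <- E[E > nb] + ns          # backbone internals shift past new tips
  att <- N + mb + 1L
  p <- E[edge_idx, 1L]; ch <- E[edge_idx, 2L]
  E[edge_idx, ] <- c(p, att)
  if (single) {
    extra <- rbind(c(att, ch), c(att, nb + 1L))
    labels <- c(backbone$tip.label, subtree)
    E2 <- NULL
  } else {
    Es <- subtree$edge
    tips <- Es <= ns
    Es[tips] <- Es[tips] + nb
    Es[!tips] <- Es[!tips] - ns + N + mb + 1L
    extra <- rbind(c(att, ch), c(att, N + mb + 2L))
    labels <- c(backbone$tip.label, subtree$tip.label)
    E2 <- Es
  }
  out <- list(edge = rbind(E, extra, E2), tip.label = labels,
              Nnode = mb + ms + 1L)
  class(out) <- "phylo"
  out
}

# Detach the subtree below edge `edge_idx`; returns the remainder plus the
# detached part (a phylo or a single tip label). NULL when the remainder
# would be degenerate (< 3 tips).
prune_edge <- function(tree, edge_idx) {
  child <- tree$edge[edge_idx, 2L]
  ntip <- ape::Ntip(tree)
  if (child <= ntip) {
    if (ntip < 4L) return(NULL)
    lab <- tree$tip.label[child]
    list(backbone = ape::drop.tip(tree, lab), subtree = lab)
  } else {
    sub <- ape::extract.clade(tree, child)
    if (ntip - ape::Ntip(sub) < 3L) return(NULL)
    list(backbone = ape::drop.tip(tree, sub$tip.label), subtree = sub)
  }
}

# All NNI rearrangements of the unrooted topology underlying a rooted binary
# tree: two swaps per internal unrooted edge.
nni_neighbors <- function(tree) {
  edge <- tree$edge
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  out <- list()
  swap2 <- function(e1, e2) {
    E <- edge
    tmp <- E[e1, 2L]
    E[e1, 2L] <- E[e2, 2L]
    E[e2, 2L] <- tmp
    nt <- tree
    nt$edge <- E
    attr(nt, "order") <- NULL
    nt
  }
  children_edges <- function(node) which(edge[, 1L] == node)
  for (k in seq_len(nrow(edge))) {
    u <- edge[k, 1L]; v <- edge[k, 2L]
    if (v <= ntip || u == root) next
    sib_edge <- setdiff(children_edges(u), k)[1L]
    for (ce in children_edges(v))
      out[[length(out) + 1L]] <- swap2(sib_edge, ce)
  }
  # the unrooted edge joining the two root children
  rc <- children_edges(root)
  if (length(rc) == 2L && all(edge[rc, 2L] > ntip)) {
    ve <- children_edges(edge[rc[1L], 2L])
    se <- children_edges(edge[rc[2L], 2L])
    out[[length(out) + 1L]] <- swap2(ve[1L], se[1L])
    out[[length(out) + 1L]] <- swap2(ve[1L], se[2L])
  }
  out
}

spr_neighbors <- function(tree) {
  out <- list()
  for (k in seq_len(nrow(tree$edge))) {
    pr <- prune_edge(tree, k)
    if (is.null(pr)) next
    for (f in seq_len(nrow(pr$backbone$edge)))
      out[[length(out) + 1L]] <- graft_on_edge(pr$backbone, pr$subtree, f)
  }
  out
}

# Contract internal edge `edge_idx` (child collapses into parent), producing
# a polytomy; used for zero-length-branch condensation.
contract_edge <- function(tree, edge_idx) {
  ntip <- ape::Ntip(tree)
  v <- tree$edge[edge_idx, 2L]
  if (v <= ntip) stop("cannot contract a terminal edge")
  u <- tree$edge[edge_idx, 1L]
  E <- tree$edge[-edge_idx, , drop = FALSE]
  E[E[, 1L] == v, 1L] <- u
  E[E > v] <- E[E > v] - 1L
  out <- list(edge = E, tip.label = tree$tip.label, Nnode = tree$Nnode - 1L)
  class(out) <- "phylo"
  out
}

#' Canonical form of an unrooted topology
#'
#' A rotation- and rooting-invariant newick-like string: two trees have the
#' same unrooted topology exactly when their canonical strings are equal.
#' Used internally to deduplicate equally parsimonious trees.
#'
#' @param tree a `phylo`.
#' @return a character scalar.
#' @export
canonical_topology <- function(tree) {
  anchor <- sort(tree$tip.label)[1L]
  tr <- ape::root(ape::unroot(tree), outgroup = anchor, resolve.root = TRUE)
  ntip <- ape::Ntip(tr)
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  lab <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    paste0("(", paste(sort(vapply(kids[[as.character(node)]], lab,
                                  character(1))), collapse = ","), ")")
  }
  lab(ntip + 1L)
}

# --- search -----------------------------------------------------------------

stepwise_addition <- function(order, discrete, continuous, weights = NULL) {
  tree <- ape::read.tree(
    text = sprintf("((%s,%s),%s);", order[1L], order[2L], order[3L]))
  for (tx in order[-(1:3)]) {
    cands <- lapply(seq_len(nrow(tree$edge)),
                    function(k) graft_on_edge(tree, tx, k))
    lens <- vapply(cands, tree_length, numeric(1),
                   discrete = discrete, continuous = continuous,
                   weights = weights)
    tree <- cands[[which.min(lens)]]
  }
  tree
}

swap_to_optimum <- function(tree, swap, discrete, continuous,
                            weights = NULL, collect_equal = TRUE,
                            max_iter = 200L) {
  neigh_fn <- switch(swap, nni = nni_neighbors, spr = spr_neighbors,
                     stop("unsupported swap type: ", swap,
                          " (use 'nni' or 'spr')"))
  len_fn <- function(t) tree_length(t, discrete, continuous, weights)
  cur <- tree; cur_len <- len_fn(tree)
  equal <- list()
  for (i in seq_len(max_iter)) {
    nb <- neigh_fn(cur)
    lens <- vapply(nb, len_fn, numeric(1))
    if (min(lens) < cur_len - 1e-9) {
      cur <- nb[[which.min(lens)]]
      cur_len <- min(lens)
    } else {
      if (collect_equal) equal <- nb[abs(lens - cur_len) < 1e-9]
      break
    }
  }
  list(tree = cur, length = cur_len, equal = equal)
}

# Minimum possible change on each edge over all most-parsimonious
# reconstructions, per the Fitch (unordered) and Wagner (additive) final
# state-set rules of Swofford & Maddison. Requires a binary tree.
branch_min_changes <- function(tree, discrete = NULL, continuous = NULL,
                               weights = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  nedge <- nrow(edge)
  mins <- numeric(nedge)
  kids <- lapply(seq_len(ntot), function(n) edge[edge[, 1L] == n, 2L])
  preorder_edges <- rev(seq_len(nedge))

  if (!is.null(discrete) && discrete$nchar > 0) {
    enc <- encode_discrete(discrete, tree$tip.label)
    nch <- discrete$nchar
    if (is.null(weights)) weights <- rep(1, nch)
    P <- matrix(0L, ntot, nch)
    P[seq_len(ntip), ] <- enc$masks
    cnt <- integer(ntot)
    for (k in seq_len(nedge)) {        # up-pass (binary)
      p <- edge[k, 1L]
      cnt[p] <- cnt[p] + 1L
      if (cnt[p] == 2L) {
        ch <- kids[[p]]
        inter <- bitwAnd(P[ch[1L], ], P[ch[2L], ])
        P[p, ] <- ifelse(inter == 0L, bitwOr(P[ch[1L], ], P[ch[2L], ]), inter)
      }
    }
    FF <- matrix(0L, ntot, nch)
    FF[root, ] <- P[root, ]
    for (k in preorder_edges) {        # down-pass
      u <- edge[k, 1L]; v <- edge[k, 2L]
      if (v <= ntip) {
        iv <- bitwAnd(P[v, ], FF[u, ])
        FF[v, ] <- ifelse(iv == 0L, P[v, ], iv)
      } else {
        ch <- kids[[v]]
        iv <- bitwAnd(P[v, ], FF[u, ])
        case1 <- iv == FF[u, ]
        inter_kids <- bitwAnd(P[ch[1L], ], P[ch[2L], ]) != 0L
        union_kids <- bitwOr(P[ch[1L], ], P[ch[2L], ])
        FF[v, ] <- ifelse(case1, FF[u, ],
                   ifelse(inter_kids,
                          bitwOr(P[v, ], bitwAnd(FF[u, ], union_kids)),
                          bitwOr(P[v, ], FF[u, ])))
      }
    }
    rc <- which(edge[, 1L] == root)
    for (k in seq_len(nedge)) {
      u <- edge[k, 1L]; v <- edge[k, 2L]
      if (u == root && length(rc) == 2L) {
        # the two root edges are halves of one unrooted edge: its minimum
        # change is fixed by the preliminary sets of the two root children
        c12 <- edge[rc, 2L]
        mins[k] <- mins[k] +
          sum(weights[bitwAnd(P[c12[1L], ], P[c12[2L], ]) == 0L])
      } else {
        mins[k] <- mins[k] +
          sum(weights[bitwAnd(FF[u, ], FF[v, ]) == 0L])
      }
    }
  }

  if (!is.null(continuous) && ncol(continuous) > 0) {
    idx <- match(tree$tip.label, rownames(continuous))
    vals <- unclass(continuous)[idx, , drop = FALSE]
    nch <- ncol(vals)
    PL <- matrix(-Inf, ntot, nch); PH <- matrix(Inf, ntot, nch)
    PL[seq_len(ntip), ][!is.na(vals)] <- vals[!is.na(vals)]
    PH[seq_len(ntip), ][!is.na(vals)] <- vals[!is.na(vals)]
    cnt <- integer(ntot)
    for (k in seq_len(nedge)) {        # up-pass (Farris intervals)
      p <- edge[k, 1L]
      cnt[p] <- cnt[p] + 1L
      if (cnt[p] == 2L) {
        ch <- kids[[p]]
        a <- pmax(PL[ch[1L], ], PL[ch[2L], ])
        b <- pmin(PH[ch[1L], ], PH[ch[2L], ])
        PL[p, ] <- pmin(a, b); PH[p, ] <- pmax(a, b)
      }
    }
    med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))
    FL <- matrix(0, ntot, nch); FH <- matrix(0, ntot, nch)
    FL[root, ] <- PL[root, ]; FH[root, ] <- PH[root, ]
    for (k in preorder_edges) {
      u <- edge[k, 1L]; v <- edge[k, 2L]
      if (v <= ntip) {
        FL[v, ] <- PL[v, ]; FH[v, ] <- PH[v, ]
      } else {
        ch <- kids[[v]]
        FL[v, ] <- med3(FL[u, ], PL[ch[1L], ], PL[ch[2L], ])
        FH[v, ] <- med3(FH[u, ], PH[ch[1L], ], PH[ch[2L], ])
      }
    }
    rc <- which(edge[, 1L] == root)
    for (k in seq_len(nedge)) {
      u <- edge[k, 1L]; v <- edge[k, 2L]
      if (u == root && length(rc) == 2L) {
        c12 <- edge[rc, 2L]
        gap <- pmax(PL[c12[1L], ], PL[c12[2L], ]) -
          pmin(PH[c12[1L], ], PH[c12[2L], ])
      } else {
        gap <- pmax(FL[u, ], FL[v, ]) - pmin(FH[u, ], FH[v, ])
      }
      gap[!is.finite(gap)] <- 0
      mins[k] <- mins[k] + sum(pmax(0, gap))
    }
  }
  list(tree = tree, mins = mins)
}

# Collapse every internal branch whose minimum length over MPRs is zero.
condense_tree <- function(tree, discrete, continuous, weights = NULL) {
  bm <- branch_min_changes(tree, discrete, continuous, weights)
  tree <- bm$tree
  ntip <- ape::Ntip(tree)
  zero_children <- tree$edge[bm$mins < 1e-9 & tree$edge[, 2L] > ntip, 2L]
  for (v in sort(zero_children, decreasing = TRUE))
    tree <- contract_edge(tree, which(tree$edge[, 2L] == v))
  tree
}

#' Heuristic parsimony search
#'
#' Random-addition-sequence starting trees followed by branch swapping (NNI
#' or SPR) to a local optimum, over the combined length of the discrete
#' (Fitch) and continuous (Farris additive) partitions. All distinct
#' topologies found at the best length are returned, rooted on the outgroup;
#' trees differing only in zero-length-branch resolutions are condensed
#' before counting. Deterministic for a fixed `seed`.
#'
#' @param discrete a [discrete_matrix()], or `NULL`.
#' @param continuous a [continuous_matrix()], or `NULL`.
#' @param outgroup taxon name used to root the result.
#' @param n_replicates number of random addition sequences.
#' @param swap `"spr"` (default) or `"nni"`.
#' @param seed optional integer seed.
#' @param weights optional per-character weights for the discrete partition.
#' @param max_trees cap on the number of distinct best trees kept.
#' @param condense collapse branches whose contraction leaves the length
#'   unchanged before counting distinct topologies.
#' @return object of class `parsimony_search`: list with `trees`
#'   (`multiPhylo`, rooted on the outgroup), `length` (best length found),
#'   and `n_replicates`.
#' @export
heuristic_search <- function(discrete = NULL, continuous = NULL, outgroup,
                             n_replicates = 10, swap = "spr", seed = NULL,
                             weights = NULL, max_trees = 100L,
                             condense = TRUE) {
  taxa <- union(if (!is.null(discrete)) discrete$taxa else character(0),
                if (!is.null(continuous)) rownames(continuous) else
                  character(0))
  if (length(taxa) < 4L) stop("need at least 4 taxa to search")
  if (!outgroup %in% taxa) stop("outgroup not found in matrix: ", outgroup)
  if (!is.null(seed)) set.seed(seed)
  best_len <- Inf
  pool <- list()       # canonical string -> tree
  for (rep in seq_len(n_replicates)) {
    ord <- sample(taxa)
    start <- stepwise_addition(ord, discrete, continuous, weights)
    res <- swap_to_optimum(start, swap, discrete, continuous, weights)
    cands <- c(list(res$tree), res$equal)
    lens <- vapply(cands, tree_length, numeric(1), discrete = discrete,
                   continuous = continuous, weights = weights)
    for (i in seq_along(cands)) {
      if (lens[i] < best_len - 1e-9) {
        best_len <- lens[i]; pool <- list()
      }
      if (abs(lens[i] - best_len) < 1e-9 && length(pool) < max_trees) {
        tr <- cands[[i]]
        if (condense) tr <- condense_tree(tr, discrete, continuous, weights)
        key <- canonical_topology(tr)
        if (is.null(pool[[key]])) pool[[key]] <- tr
      }
    }
  }
  trees <- lapply(pool, function(tr)
    ape::root(ape::unroot(tr), outgroup = outgroup, resolve.root = TRUE))
  names(trees) <- NULL
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, length = best_len,
                 n_replicates = n_replicates),
            class = "parsimony_search")
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("Heuristic parsimony search:", length(x$trees),
      "best tree(s) of length", x$length, "from", x$n_replicates,
      "addition replicates\n")
  invisible(x)
}

# --- node support -----------------------------------------------------------

# Non-trivial unrooted splits as canonical strings (side not containing the
# alphabetically first tip, tips sorted and joined).
tree_splits <- function(tree) {
  ntip <- ape::Ntip(tree)
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[1L]
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (i in seq_along(pp)) {
    clade <- tree$tip.label[pp[[i]]]
    if (anchor %in% clade) clade <- setdiff(all_tips, clade)
    if (length(clade) >= 2L && length(clade) <= ntip - 2L)
      out <- c(out, paste(sort(clade), collapse = "|"))
  }
  unique(out)
}

#' Symmetric-resampling node support
#'
#' Perturbs character weights symmetrically (each character doubled with
#' probability `p_change/2`, halved with probability `p_change/2`, unchanged
#' otherwise), reruns a reduced parsimony search per replicate, and reports
#' for each internal node of `tree` the fraction of replicates whose strict
#' consensus of best trees retains the corresponding bipartition. The
#' per-replicate searches use fewer addition sequences and NNI swapping, the
#' usual economy for resampling support.
#'
#' @inheritParams heuristic_search
#' @param tree reference tree whose internal nodes are scored.
#' @param n_reps number of resampling replicates.
#' @param p_change total probability that a character's weight is perturbed;
#'   default 1/3.
#' @param search_replicates addition sequences per replicate search.
#' @param swap swap type for the per-replicate searches (default `"nni"`).
#' @return data.frame of class `support_table` with columns `node` (internal
#'   node number in `tree`), `split` (canonical bipartition string) and
#'   `support` (frequency in \[0, 1\]).
#' @export
symmetric_resampling <- function(discrete, continuous = NULL, tree,
                                 n_reps = 100, p_change = 1/3, seed = NULL,
                                 search_replicates = 1, swap = "nni") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (p_change < 0 || p_change >= 1) stop("p_change must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  ref_splits <- tree_splits(tree)
  counts <- setNames(numeric(length(ref_splits)), ref_splits)
  nch <- discrete$nchar
  for (rep in seq_len(n_reps)) {
    u <- stats::runif(nch)
    w <- ifelse(u < p_change / 2, 2, ifelse(u < p_change, 0.5, 1))
    res <- heuristic_search(discrete, continuous,
                            outgroup = tree$tip.label[1L],
                            n_replicates = search_replicates, swap = swap,
                            weights = w, condense = FALSE)
    rep_splits <- Reduce(intersect, lapply(res$trees, tree_splits))
    hit <- ref_splits %in% rep_splits
    counts[hit] <- counts[hit] + 1
  }
  # map splits back to internal nodes of the reference tree
  pp <- ape::prop.part(tree)
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[1L]
  node <- integer(0); split <- character(0)
  for (i in seq_along(pp)) {
    clade <- tree$tip.label[pp[[i]]]
    if (anchor %in% clade) clade <- setdiff(all_tips, clade)
    key <- paste(sort(clade), collapse = "|")
    if (key %in% ref_splits) {
      node <- c(node, ntip + i)
      split <- c(split, key)
    }
  }
  structure(data.frame(node = node, split = split,
                       support = counts[split] / n_reps,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("support_table", "data.frame"))
}
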