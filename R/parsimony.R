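# Parsimony tree lengths: Fitch (unordered discrete) and Farris intervals
# (continuous/additive), vectorised across characters with bitmask state sets.

# Encode a discrete matrix as bitmasks, rows ordered as `tip_order`.
# Missing cells get the union of states observed in that character, so they
# never force a step. Limited to states 0..29 (integer bitmasks).
encode_discrete <- function(m, tip_order) {
  idx <- match(tip_order, m$taxa)
  if (anyNA(idx))
    stop("tip(s) absent from matrix: ",
         paste(tip_order[is.na(idx)], collapse = ", "))
  ntip <- length(tip_order); nch <- m$nchar
  masks <- matrix(0L, ntip, nch)
  full <- integer(nch)
  for (j in seq_len(nch)) {
    col <- m$states[, j]
    fm <- 0L
    cm <- integer(length(col))
    for (i in seq_along(col)) {
      st <- col[[i]]
      if (cell_is_missing(st)) cm[i] <- NA_integer_
      else {
        if (any(st > 29L)) stop("states above 29 not supported")
        v <- sum(bitwShiftL(1L, st))
        cm[i] <- v
        fm <- bitwOr(fm, v)
      }
    }
    if (fm == 0L) fm <- 1L            # character with no data: inert
    cm[is.na(cm)] <- fm
    full[j] <- fm
    masks[, j] <- cm[idx]
  }
  list(masks = masks, full = full)
}

# Core Fitch pass over a postorder edge matrix. Polytomies are folded
# child-by-child (standard sequential Fitch generalisation).
fitch_pass <- function(edge, n_node_total, tip_masks) {
  nch <- ncol(tip_masks)
  ntip <- nrow(tip_masks)
  node_masks <- matrix(0L, n_node_total, nch)
  node_masks[seq_len(ntip), ] <- tip_masks
  seen <- logical(n_node_total)
  steps <- numeric(nch)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    cm <- node_masks[ch, ]
    if (!seen[p]) {
      node_masks[p, ] <- cm
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(node_masks[p, ], cm)
      zero <- inter == 0L
      steps <- steps + zero
      node_masks[p, ] <- ifelse(zero, bitwOr(node_masks[p, ], cm), inter)
    }
  }
  steps
}

#' Fitch parsimony length for unordered discrete characters
#'
#' Computes the minimum number of state changes on a tree under Fitch
#' parsimony. Polymorphic cells contribute their whole state set at the tip
#' (ambiguity semantics); missing cells contribute the union of states
#' observed for that character and therefore never add steps. The length is
#' invariant to the position of the root.
#'
#' @param tree an `ape::phylo`; polytomies are allowed (folded sequentially).
#' @param m a [discrete_matrix()] whose taxa include all tips of `tree`.
#' @param weights optional per-character weights (default 1).
#' @param per_char if `TRUE`, return the per-character step vector instead of
#'   the weighted total.
#' @return total weighted steps (numeric scalar), or a per-character vector.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' m <- discrete_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' fitch_length(tr, m)  # 1
#' @export
fitch_length <- function(tree, m, weights = NULL, per_char = FALSE) {
  if (m$nchar == 0L) return(if (per_char) numeric(0) else 0)
  enc <- encode_discrete(m, tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  steps <- fitch_pass(tree$edge, ape::Ntip(tree) + tree$Nnode, enc$masks)
  if (per_char) return(steps)
  if (is.null(weights)) weights <- rep(1, m$nchar)
  sum(steps * weights)
}

#' Farris (additive) parsimony length for continuous characters
#'
#' Continuous characters are treated as additive: the length of a character
#' on the tree is the minimal possible sum of absolute parent-child
#' differences over all assignments of internal values, computed by the
#' Farris interval algorithm. Missing cells impose no constraint.
#'
#' @inheritParams fitch_length
#' @param m a [continuous_matrix()].
#' @return total weighted length (numeric), or per-character vector.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' m <- continuous_matrix(rbind(A = 0.1, B = 0.2, C = 0.5))
#' farris_length(tr, m)  # 0.4
#' @export
farris_length <- function(tree, m, weights = NULL, per_char = FALSE) {
  if (ncol(m) == 0L) return(if (per_char) numeric(0) else 0)
  idx <- match(tree$tip.label, rownames(m))
  if (anyNA(idx))
    stop("tip(s) absent from matrix: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  vals <- unclass(m)[idx, , drop = FALSE]
  nch <- ncol(vals); ntip <- nrow(vals)
  lo <- vals; hi <- vals
  lo[is.na(lo)] <- -Inf; hi[is.na(hi)] <- Inf
  tree <- ape::reorder.phylo(tree, "postorder")
  ntot <- ntip + tree$Nnode
  LO <- matrix(0, ntot, nch); HI <- matrix(0, ntot, nch)
  LO[seq_len(ntip), ] <- lo; HI[seq_len(ntip), ] <- hi
  seen <- logical(ntot)
  steps <- numeric(nch)
  edge <- tree$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    if (!seen[p]) {
      LO[p, ] <- LO[ch, ]; HI[p, ] <- HI[ch, ]
      seen[p] <- TRUE
    } else {
      a <- pmax(LO[p, ], LO[ch, ])
      b <- pmin(HI[p, ], HI[ch, ])
      gap <- a - b
      gap[!is.finite(gap)] <- 0     # at least one side unconstrained
      steps <- steps + pmax(0, gap)
      LO[p, ] <- pmin(a, b); HI[p, ] <- pmax(a, b)
    }
  }
  if (per_char) return(steps)
  if (is.null(weights)) weights <- rep(1, nch)
  sum(steps * weights)
}

# Combined length used by the heuristic search.
tree_length <- function(tree, discrete = NULL, continuous = NULL,
                        weights = NULL) {
  len <- 0
  if (!is.null(discrete) && discrete$nchar > 0)
    len <- len + fitch_length(tree, discrete, weights = weights)
  if (!is.null(continuous) && ncol(continuous) > 0)
    len <- len + farris_length(tree, continuous)
  len
}

#' Ensemble parsimony fit indices (CI, HI, RI)
#'
#' Computes observed steps `s`, minimum steps `m` and maximum steps `g` per
#' discrete character on a tree, and the ensemble consistency index
#' `CI = sum(m)/sum(s)`, homoplasy index `HI = 1 - CI` and retention index
#' `RI = (sum(g) - sum(s)) / (sum(g) - sum(m))`.
#'
#' Minimum steps count one change fewer than the number of states observed in
#' unambiguous (singleton) cells, consistent with the ambiguity semantics of
#' [fitch_length()] (a state scored only inside polymorphic sets need never
#' be realised, so it cannot force a step). Maximum steps for an unordered
#' character are the number of scored tips minus the largest count
#' achievable by a single state, with polymorphic tips counted toward their
#' most favourable state.
#'
#' @inheritParams fitch_length
#' @return object of class `parsimony_fit`: list with `length`, `per_char`
#'   (data.frame `s`, `m`, `g`), `CI`, `HI`, `RI`. `RI` is `NA` (flagged via
#'   `ri_defined = FALSE`) when `sum(g) == sum(m)`, e.g. for a matrix of
#'   constant characters.
#' @export
fit_indices <- function(tree, m) {
  s <- fitch_length(tree, m, per_char = TRUE)
  mm <- numeric(m$nchar); gg <- numeric(m$nchar)
  for (j in seq_len(m$nchar)) {
    col <- m$states[, j]
    scored <- !vapply(col, cell_is_missing, logical(1))
    sets <- col[scored]
    if (!length(sets)) { mm[j] <- 0; gg[j] <- 0; next }
    singleton_states <- unique(unlist(sets[lengths(sets) == 1L]))
    mm[j] <- max(0L, length(singleton_states) - 1L)
    all_states <- sort(unique(unlist(sets)))
    best <- max(vapply(all_states, function(st)
      sum(vapply(sets, function(x) st %in% x, logical(1))), integer(1)))
    gg[j] <- length(sets) - best
  }
  Ss <- sum(s); Sm <- sum(mm); Sg <- sum(gg)
  ci <- if (Ss > 0) Sm / Ss else 1
  ri_defined <- Sg > Sm
  ri <- if (ri_defined) (Sg - Ss) / (Sg - Sm) else NA_real_
  structure(
    list(length = Ss,
         per_char = data.frame(s = s, m = mm, g = gg),
         CI = ci, HI = 1 - ci, RI = ri, ri_defined = ri_defined),
    class = "parsimony_fit")
}

#' @export
print.parsimony_fit <- function(x, ...) {
  cat(sprintf("Tree length %g steps; CI = %.3f, HI = %.3f, RI = %s\n",
              x$length, x$CI, x$HI,
              if (x$ri_defined) sprintf("%.3f", x$RI) else "undefined"))
  invisible(x)
}
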