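# Phylogenetic independent contrasts and axis-wise correlation between the
# continuous-character (PCA) and discrete-character (PCoA) morphospaces.

#' Phylogenetic independent contrasts
#'
#' Felsenstein's contrasts for one or more variables on a dated binary
#' tree (computed via \pkg{ape}): each contrast is the difference between
#' the two daughter values scaled by the square root of the summed branch
#' lengths, with node values taken as branch-length-weighted averages and
#' parent branches lengthened accordingly. Zero-length branches are
#' perturbed by a small constant first.
#'
#' @param tree dated binary `phylo` with branch lengths.
#' @param tip_values named numeric vector, or matrix with taxa as rownames.
#' @return matrix of standardized contrasts (one row per internal node, one
#'   column per variable).
#' @export
pic_contrasts <- function(tree, tip_values) {
  if (!ape::is.binary(tree)) stop("contrasts require a fully binary tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tree <- ensure_positive_lengths(tree)
  v <- if (is.matrix(tip_values)) tip_values
       else matrix(tip_values, dimnames = list(names(tip_values), NULL))
  miss <- setdiff(tree$tip.label, rownames(v))
  if (length(miss)) stop("missing tip values for: ",
                         paste(miss, collapse = ", "))
  v <- v[tree$tip.label, , drop = FALSE]
  out <- apply(v, 2, function(x)
    ape::pic(stats::setNames(x, tree$tip.label), tree))
  matrix(out, ncol = ncol(v), dimnames = list(NULL, colnames(v)))
}

#' Axis-wise correlations between two morphospaces, on contrasts
#'
#' Pairs ordination axes positionally (axis 1 with axis 1, and so on),
#' transforms both score vectors into phylogenetic independent contrasts,
#' and reports the Pearson correlation of the contrasts. The standard
#' convention forces the regression through the origin (contrasts have
#' arbitrary sign); `through_origin = FALSE` gives the plain correlation.
#' Because ordination axis orientations are arbitrary, `abs_r` is reported
#' alongside the signed `r`.
#'
#' @param pc_scores,pco_scores [`ordination`][pca_ordination] objects or
#'   score matrices over the same taxa.
#' @param tree dated binary `phylo`.
#' @param k number of leading axis pairs to correlate.
#' @param through_origin correlate contrasts through the origin (default).
#' @return data.frame with columns `axis`, `r`, `abs_r`, `p`.
#' @export
axis_correlations <- function(pc_scores, pco_scores, tree, k,
                              through_origin = TRUE) {
  a <- member_scores(pc_scores)
  b <- member_scores(pco_scores)
  if (!setequal(rownames(a), rownames(b)))
    stop("the two score sets cover different taxa")
  b <- b[rownames(a), , drop = FALSE]
  if (k > min(ncol(a), ncol(b)))
    stop("k exceeds the available axes (", min(ncol(a), ncol(b)), ")")
  ca <- pic_contrasts(tree, a[, seq_len(k), drop = FALSE])
  cb <- pic_contrasts(tree, b[, seq_len(k), drop = FALSE])
  n <- nrow(ca)
  rows <- lapply(seq_len(k), function(i) {
    x <- ca[, i]; y <- cb[, i]
    if (through_origin) {
      den <- sqrt(sum(x^2) * sum(y^2))
      r <- if (den > 0) sum(x * y) / den else 0
      df <- n - 1
    } else {
      r <- stats::cor(x, y)
      df <- n - 2
    }
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    data.frame(axis = i, r = r, abs_r = abs(r),
               p = 2 * stats::pt(-abs(tstat), df))
  })
  do.call(rbind, rows)
}
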