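# Morphospace construction: log-ratio + mean imputation + PCA for the
# continuous characters, MORD distances + PCoA for the discrete characters.

#' Log-ratio transformation of a continuous ratio matrix
#'
#' Elementwise natural log of the (strictly positive) ratio characters,
#' correcting the spurious correlations that arise among ratios sharing
#' terms. A centred variant (`centre = TRUE`) additionally subtracts each
#' taxon's row mean of the logged values (centred log-ratio).
#'
#' @param m a [continuous_matrix()].
#' @param centre apply row-centring after logging (default `FALSE`).
#' @return a `continuous_matrix`-shaped numeric matrix of logged values
#'   (values may be negative; missing preserved).
#' @export
logratio_transform <- function(m, centre = FALSE) {
  v <- unclass(m)
  if (any(v <= 0, na.rm = TRUE))
    stop("log-ratio transform requires strictly positive values")
  out <- log(v)
  if (centre) out <- out - rowMeans(out, na.rm = TRUE)
  out
}

#' Mean-value imputation of missing cells
#'
#' Each missing cell is replaced by the mean of its character over the
#' scored taxa, leaving per-character means unchanged.
#'
#' @param m numeric matrix (taxa x characters), possibly with `NA`.
#' @return the completed matrix.
#' @export
mean_impute <- function(m) {
  v <- unclass(m)
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (all(miss)) stop("character ", j, " has no scored values to impute from")
    if (any(miss)) v[miss, j] <- mean(v[!miss, j])
  }
  v
}

#' Principal component analysis of a complete character matrix
#'
#' Eigendecomposition of the character covariance matrix (variance-based
#' PCA, the convention for commensurable log-transformed ratios). Total
#' variance is conserved: the axis variances sum to the total variance of
#' the input.
#'
#' @param m complete numeric matrix, taxa x characters (rownames = taxa).
#' @return object of class `ordination`: list with `taxa`, `scores`
#'   (taxa x axes, centred), `axis_variances` (eigenvalues, non-increasing),
#'   `method = "PCA"`, `n_positive` (count of axes with positive variance).
#' @export
pca_ordination <- function(m) {
  v <- unclass(m)
  if (nrow(v) < 2) stop("PCA needs at least 2 taxa")
  if (anyNA(v)) stop("matrix must be complete (impute first)")
  p <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  scores <- p$x
  rownames(scores) <- rownames(v)
  structure(list(taxa = rownames(v), scores = scores, axis_variances = ev,
                 method = "PCA", n_positive = sum(ev > 1e-12)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(x$method, "ordination:", length(x$taxa), "taxa,",
      ncol(x$scores), "axes (", x$n_positive, "with positive variance )\n")
  invisible(x)
}

#' Maximum observable rescaled distance (MORD)
#'
#' Pairwise dissimilarity between taxa of a discrete matrix: the sum of
#' per-character differences divided by the sum of the maximum possible
#' differences, both over the characters scored in both taxa. For an
#' unordered character the difference is 0 when the state sets intersect
#' and 1 otherwise (maximum 1); for an ordered character it is the minimum
#' absolute state difference across the two sets rescaled by the character's
#' observed state range (maximum 1). Pairs with no mutually scored
#' characters are flagged incomparable and, by default, filled with the
#' maximum observed distance (with a warning); `incomparable = "na"` leaves
#' them `NA`.
#'
#' @param m a [discrete_matrix()].
#' @param incomparable `"max"` (default) or `"na"`.
#' @return object of class `mord_distance`: list with `taxa`, `distances`
#'   (symmetric matrix in `[0,1]`, zero diagonal), `comparable` (matrix of
#'   mutually scored character counts), `incomparable_pairs` (two-column
#'   matrix of taxon names, possibly empty).
#' @export
mord <- function(m, incomparable = c("max", "na")) {
  incomparable <- match.arg(incomparable)
  n <- length(m$taxa)
  if (n < 2) stop("need at least 2 taxa")
  nch <- m$nchar
  # per-character observed range for ordered rescaling
  rng <- vapply(seq_len(nch), function(j) {
    st <- unlist(m$states[, j])
    st <- st[!is.na(st)]
    if (length(st) < 2) 1 else max(1, diff(range(st)))
  }, numeric(1))
  D <- matrix(0, n, n, dimnames = list(m$taxa, m$taxa))
  W <- matrix(0L, n, n, dimnames = list(m$taxa, m$taxa))
  scored <- !matrix(vapply(m$states, cell_is_missing, logical(1)),
                    n, nch)
  for (i in seq_len(n - 1)) for (k in (i + 1):n) {
    both <- which(scored[i, ] & scored[k, ])
    W[i, k] <- W[k, i] <- length(both)
    if (!length(both)) { D[i, k] <- D[k, i] <- NA_real_; next }
    num <- 0; den <- 0
    for (j in both) {
      a <- m$states[[i, j]]; b <- m$states[[k, j]]
      if (m$ordering[j] == "ordered") {
        d <- min(abs(outer(a, b, "-"))) / rng[j]
      } else {
        d <- as.numeric(length(intersect(a, b)) == 0L)
      }
      num <- num + d; den <- den + 1
    }
    D[i, k] <- D[k, i] <- num / den
  }
  inc <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  pairs <- cbind(m$taxa[inc[, 1L]], m$taxa[inc[, 2L]])
  if (nrow(inc) && incomparable == "max") {
    mx <- max(D, na.rm = TRUE)
    warning(nrow(inc), " incomparable pair(s) filled with the maximum ",
            "observed distance ", signif(mx, 3))
    D[is.na(D)] <- mx
    diag(D) <- 0
  }
  structure(list(taxa = m$taxa, distances = D, comparable = W,
                 incomparable_pairs = pairs),
            class = "mord_distance")
}

#' Principal coordinate analysis
#'
#' Classical (metric) multidimensional scaling: double-centring of
#' `-0.5 * D^2` followed by eigendecomposition. No correction is applied to
#' negative eigenvalues; all axes are returned with their eigenvalue signs
#' so that the count of positive-variance axes is observable.
#'
#' @param d a `mord_distance`, `dist`, or complete symmetric numeric matrix.
#' @return object of class `ordination` with `method = "PCoA"`: `scores`
#'   holds coordinates on axes with positive eigenvalue; `axis_variances`
#'   holds all eigenvalues (positive and negative, non-increasing);
#'   `n_positive` counts positive-variance axes.
#' @export
pcoa_ordination <- function(d) {
  if (inherits(d, "mord_distance")) {
    taxa <- d$taxa; D <- d$distances
  } else if (inherits(d, "dist")) {
    D <- as.matrix(d); taxa <- rownames(D)
  } else {
    D <- as.matrix(d); taxa <- rownames(D)
  }
  if (anyNA(D)) stop("distance matrix has NA entries; resolve them first")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  A <- -0.5 * D^2
  centred <- A - rowMeans(A)[row(A)] - colMeans(A)[col(A)] + mean(A)
  e <- eigen(centred, symmetric = TRUE)
  ev <- e$values
  # eigenvalues of magnitude ~0 are numerical noise, not real variance
  tol <- 1e-9 * max(1, abs(ev[1L]))
  ev[abs(ev) < tol] <- 0
  pos <- which(ev > 0)
  scores <- if (length(pos))
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  else matrix(numeric(0), n, 0)
  dimnames(scores) <- list(taxa,
                           if (length(pos)) paste0("PCo", seq_along(pos)))
  structure(list(taxa = taxa, scores = scores,
                 axis_variances = ev / (n - 1), eigenvalues = ev,
                 method = "PCoA", n_positive = length(pos),
                 negative_eigenvalues = any(ev < 0)),
            class = "ordination")
}
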