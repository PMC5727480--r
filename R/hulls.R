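# Convex-hull morphospace occupation by group (diet), with pairwise hull
# overlap via convex polygon clipping.

# Shoelace area of a polygon given as a 2-column matrix of vertices.
polygon_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# Counter-clockwise convex hull of 2D points.
convex_hull <- function(p) {
  idx <- grDevices::chull(p[, 1], p[, 2])
  h <- p[idx, , drop = FALSE]
  n <- nrow(h)
  if (n >= 3) {
    i2 <- c(2:n, 1)
    signed <- sum(h[, 1] * h[i2, 2] - h[i2, 1] * h[, 2]) / 2
    if (signed < 0) h <- h[n:1, , drop = FALSE]
  }
  h
}

# Sutherland-Hodgman clipping of (convex) polygon `subject` by convex
# polygon `clip` (both counter-clockwise); returns the intersection polygon.
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(matrix(numeric(0), 0, 2))
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
      (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      d1 <- c(q[1] - p[1], q[2] - p[2])
      d2 <- c(b[1] - a[1], b[2] - a[2])
      den <- d2[1] * d1[2] - d2[2] * d1[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / -den
      p + t * d1
    }
    res <- list()
    n <- nrow(out)
    for (j in seq_len(n)) {
      p <- out[j, ]; q <- out[if (j == n) 1 else j + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin && qin) res[[length(res) + 1]] <- q
      else if (pin && !qin) res[[length(res) + 1]] <- inter(p, q)
      else if (!pin && qin) {
        res[[length(res) + 1]] <- inter(p, q)
        res[[length(res) + 1]] <- q
      }
    }
    out <- if (length(res)) do.call(rbind, res) else matrix(numeric(0), 0, 2)
  }
  out
}

#' Convex-hull areas and pairwise overlaps of groups in morphospace
#'
#' Computes the 2D convex hull area of each group's taxa on two ordination
#' axes, and the area of pairwise hull intersections (convex polygon
#' clipping). Groups with fewer than 3 distinct points have degenerate
#' hulls of area 0.
#'
#' @param scores an [`ordination`][pca_ordination] or score matrix.
#' @param groups named character vector or factor: group label per taxon
#'   (names = taxon names), e.g. diet categories.
#' @param axes two axis indices (default first two).
#' @return list with `areas` (named numeric per group) and `overlap`
#'   (symmetric matrix of pairwise intersection areas).
#' @export
convex_hull_areas <- function(scores, groups, axes = c(1, 2)) {
  s <- member_scores(scores, NULL, axes)
  if (length(axes) != 2) stop("hull areas are computed on exactly 2 axes")
  groups <- groups[rownames(s)]
  if (anyNA(groups)) stop("group label missing for some taxa")
  levs <- unique(as.character(groups))
  hulls <- lapply(levs, function(g) {
    p <- s[as.character(groups) == g, , drop = FALSE]
    if (nrow(p) < 3) return(p)
    convex_hull(p)
  })
  names(hulls) <- levs
  areas <- vapply(hulls, polygon_area, numeric(1))
  ov <- matrix(0, length(levs), length(levs), dimnames = list(levs, levs))
  if (length(levs) > 1) {
    for (i in seq_len(length(levs) - 1)) for (j in (i + 1):length(levs)) {
      hi <- hulls[[i]]; hj <- hulls[[j]]
      if (nrow(hi) >= 3 && nrow(hj) >= 3)
        ov[i, j] <- ov[j, i] <- polygon_area(clip_convex(hi, hj))
    }
  }
  diag(ov) <- areas
  list(areas = areas, overlap = ov)
}
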