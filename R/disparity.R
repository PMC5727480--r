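# Time-binned disparity: bin membership, sum of variances / ranges, taxon
# bootstrap, and the scaled centre-of-gravity (CGS) clade-shape statistic.

#' Assign taxa to time bins by stratigraphic range overlap
#'
#' A taxon belongs to every bin its range `[fad, lad]` overlaps with
#' positive length (range-through taxa appear in all spanned bins). A taxon
#' touching a bin boundary with zero overlap (including point occurrences,
#' `fad == lad`) is assigned to the older bin only. Taxa overlapping no bin
#' are dropped with a warning.
#'
#' @param taxa a [taxon_records()] table.
#' @param bins a [time_bins()] set.
#' @return named list (one element per bin, old to young) of member taxon
#'   name vectors, of class `bin_membership`.
#' @export
assign_bins <- function(taxa, bins) {
  out <- lapply(seq_len(nrow(bins)), function(i) {
    start <- bins$start[i]; end <- bins$end[i]
    L <- pmin(taxa$fad, start) - pmax(taxa$lad, end)
    touch <- abs(L) < 1e-12
    member <- L > 1e-12 | (touch & abs(pmax(taxa$lad, end) - end) < 1e-12)
    taxa$name[member]
  })
  names(out) <- bins$name
  orphan <- setdiff(taxa$name, unlist(out))
  if (length(orphan))
    warning("taxa outside all bins, excluded: ",
            paste(orphan, collapse = ", "))
  structure(out, class = "bin_membership")
}

#' Disparity metrics over a set of taxa
#'
#' `sum_of_variances` is the sum over the selected ordination axes of the
#' sample variance (n-1 denominator) of the member scores; it is `NA`
#' (undefined) for fewer than two members. `sum_of_ranges` is the sum over
#' axes of the score range (max minus min); singletons give 0 and an empty
#' member set is an error.
#'
#' @param scores an [`ordination`][pca_ordination] object or a numeric score
#'   matrix with taxa as rownames.
#' @param members taxon names to include (default: all rows).
#' @param axes columns of the score matrix to use (default: all).
#' @return a single numeric value.
#' @export
sum_of_variances <- function(scores, members = NULL, axes = NULL) {
  s <- member_scores(scores, members, axes)
  if (nrow(s) < 2) return(NA_real_)
  sum(apply(s, 2, stats::var))
}

#' @rdname sum_of_variances
#' @export
sum_of_ranges <- function(scores, members = NULL, axes = NULL) {
  s <- member_scores(scores, members, axes)
  if (nrow(s) == 0) stop("empty member set has no range")
  sum(apply(s, 2, function(x) diff(range(x))))
}

member_scores <- function(scores, members = NULL, axes = NULL) {
  s <- if (inherits(scores, "ordination")) scores$scores else as.matrix(scores)
  if (!is.null(members)) {
    miss <- setdiff(members, rownames(s))
    if (length(miss)) stop("taxa missing from scores: ",
                           paste(miss, collapse = ", "))
    s <- s[members, , drop = FALSE]
  }
  if (!is.null(axes)) s <- s[, axes, drop = FALSE]
  s
}

#' Taxon-bootstrap confidence interval for a disparity metric
#'
#' Resamples the member taxa with replacement, recomputes the metric, and
#' reports the 2.5/97.5 percentile interval.
#'
#' @inheritParams sum_of_variances
#' @param metric `"sov"` (sum of variances) or `"sor"` (sum of ranges).
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed optional integer seed.
#' @return list with `estimate`, `ci` (length-2 numeric), `n_boot`.
#' @export
bootstrap_disparity <- function(scores, members = NULL, axes = NULL,
                                metric = c("sov", "sor"), n_boot = 1000,
                                seed = NULL) {
  metric <- match.arg(metric)
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  s <- member_scores(scores, members, axes)
  fn <- if (metric == "sov") sum_of_variances else sum_of_ranges
  est <- fn(s)
  reps <- vapply(seq_len(n_boot), function(b) {
    fn(s[sample.int(nrow(s), replace = TRUE), , drop = FALSE])
  }, numeric(1))
  list(estimate = est,
       ci = unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE)),
       n_boot = n_boot)
}

#' Per-bin score matrices
#'
#' Splits an ordination's score matrix into one matrix per time bin
#' according to a [assign_bins()] membership; the result feeds
#' [disparity_profile()] and [cgs_bootstrap()], and has the same shape as
#' the ghost-augmented sets from [ghost_lineage_scores()].
#'
#' @param scores an [`ordination`][pca_ordination] or score matrix.
#' @param membership a `bin_membership` list.
#' @param axes optional axis selection.
#' @return list of class `bin_scores`.
#' @export
bin_scores <- function(scores, membership, axes = NULL) {
  out <- lapply(membership, function(mem)
    member_scores(scores, mem, axes))
  structure(out, class = "bin_scores")
}

#' Disparity-through-time profile
#'
#' Computes a disparity value per time bin with taxon-bootstrap confidence
#' intervals, from per-bin score sets (see [bin_scores()] /
#' [ghost_lineage_scores()]).
#'
#' @param bscores a `bin_scores` list (per-bin score matrices).
#' @param metric `"sov"` or `"sor"`.
#' @param n_boot bootstrap replicates for the CI; 0 disables.
#' @param seed optional integer seed.
#' @return data.frame of class `disparity_profile` with columns `bin`, `n`,
#'   `n_ghost`, `value`, `ci_lo`, `ci_hi`. Bins with fewer members than the
#'   metric requires get `NA` values.
#' @export
disparity_profile <- function(bscores, metric = c("sov", "sor"),
                              n_boot = 0, seed = NULL) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  fn <- if (metric == "sov") sum_of_variances else sum_of_ranges
  rows <- lapply(names(bscores), function(bn) {
    s <- bscores[[bn]]
    ghosts <- sum(grepl("^ghost:", rownames(s)))
    n <- nrow(s)
    ok <- if (metric == "sov") n >= 2 else n >= 1
    val <- if (ok) fn(s) else NA_real_
    ci <- c(NA_real_, NA_real_)
    if (ok && n_boot > 0) {
      reps <- vapply(seq_len(n_boot), function(b)
        fn(s[sample.int(n, replace = TRUE), , drop = FALSE]), numeric(1))
      ci <- unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE))
    }
    data.frame(bin = bn, n = n, n_ghost = ghosts, value = val,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("disparity_profile", "data.frame"))
}

#' Scaled centre of gravity of a disparity profile
#'
#' `CG = sum(d_i * t_i) / sum(d_i)` where `t_i` is the bin midpoint rescaled
#' onto the clade's time axis: 0 at the start of the oldest occupied bin, 1
#' at the end of the youngest. Values below 0.5 indicate a bottom-heavy
#' (early-disparity) clade, above 0.5 a top-heavy one. Because bins may have
#' unequal durations, the null expectation is the CG of a flat profile over
#' the same occupied bins rather than 0.5 exactly.
#'
#' @param values per-bin disparity values (or a `disparity_profile`); `NA`
#'   bins are treated as unoccupied.
#' @param bins the corresponding [time_bins()].
#' @return list of class `cgs_result`: `cgs`, `null` (flat-profile CG),
#'   `occupied` (logical per bin).
#' @export
cgs <- function(values, bins) {
  if (inherits(values, "disparity_profile")) values <- values$value
  if (length(values) != nrow(bins))
    stop("profile length does not match number of bins")
  occ <- !is.na(values)
  if (sum(occ) < 3) stop("need at least 3 occupied bins")
  d <- values[occ]
  if (all(d == 0)) stop("all-zero disparity profile has no centre of gravity")
  start0 <- max(bins$start[occ])          # oldest occupied bin start (Ma)
  end1 <- min(bins$end[occ])              # youngest occupied bin end (Ma)
  mid <- (bins$start[occ] + bins$end[occ]) / 2
  t <- (start0 - mid) / (start0 - end1)
  structure(list(cgs = sum(d * t) / sum(d), null = mean(t), occupied = occ),
            class = "cgs_result")
}

#' @export
print.cgs_result <- function(x, ...) {
  cat(sprintf("CGS = %.4f (flat-profile null = %.4f)%s\n", x$cgs, x$null,
              if (!is.null(x$p_value))
                sprintf(", bootstrap p = %.3f (n = %d)", x$p_value, x$n_boot)
              else ""))
  invisible(x)
}

#' CGS with taxon-bootstrap significance test
#'
#' Recomputes the disparity profile and its CGS under taxon bootstrapping
#' (resampling members with replacement within each bin) and reports a
#' two-tailed percentile p-value for the deviation of the CGS from the
#' flat-profile null expectation.
#'
#' @param bscores per-bin score sets ([bin_scores()] or
#'   [ghost_lineage_scores()] output).
#' @param bins the corresponding [time_bins()].
#' @param metric `"sov"` or `"sor"`.
#' @param n_boot bootstrap replicates.
#' @param seed optional integer seed.
#' @return `cgs_result` with added `p_value`, `boot` (replicate CGS values)
#'   and `n_boot`.
#' @export
cgs_bootstrap <- function(bscores, bins, metric = c("sov", "sor"),
                          n_boot = 1000, seed = NULL) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  base_profile <- disparity_profile(bscores, metric)
  res <- cgs(base_profile, bins)
  fn <- if (metric == "sov") sum_of_variances else sum_of_ranges
  boot <- vapply(seq_len(n_boot), function(b) {
    vals <- vapply(bscores, function(s) {
      n <- nrow(s)
      ok <- if (metric == "sov") n >= 2 else n >= 1
      if (!ok) return(NA_real_)
      fn(s[sample.int(n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
    out <- tryCatch(cgs(vals, bins)$cgs, error = function(e) NA_real_)
    out
  }, numeric(1))
  boot_ok <- boot[!is.na(boot)]
  p <- if (length(boot_ok))
    min(1, 2 * min(mean(boot_ok <= res$null), mean(boot_ok >= res$null)))
  else NA_real_
  res$p_value <- p
  res$boot <- boot
  res$n_boot <- n_boot
  res
}

#' Taxon counts per bin and diet category
#'
#' @param taxa a [taxon_records()] table with diet labels.
#' @param bins a [time_bins()] set.
#' @return data.frame, one row per bin, with columns `bin`, `carnivore`,
#'   `omnivore`, `herbivore` (and `unknown` when present) and `total`.
#' @export
diet_counts <- function(taxa, bins) {
  membership <- suppressWarnings(assign_bins(taxa, bins))
  diets <- c("carnivore", "omnivore", "herbivore")
  if (any(taxa$diet == "unknown")) diets <- c(diets, "unknown")
  rows <- lapply(names(membership), function(bn) {
    mem <- membership[[bn]]
    d <- taxa$diet[match(mem, taxa$name)]
    counts <- vapply(diets, function(x) sum(d == x), integer(1))
    cbind(data.frame(bin = bn, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)), data.frame(total = length(mem)))
  })
  do.call(rbind, rows)
}
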