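# Node-age calibration from stratigraphically consistent outgroup ages
# (Hedman's Bayesian approach, applied across a whole tree in the manner of
# Lloyd et al.), and stratigraphic time-bin construction.

#' Hedman posterior for a single node age
#'
#' Computes the discretised posterior age distribution of a node given the
#' first-appearance ages of its successive outgroups, assuming each
#' divergence is uniformly distributed between its bounding ages: the
#' deepest divergence is uniform between the oldest outgroup's age and
#' `t_max`, each subsequent divergence uniform between its outgroup's age
#' and the previous divergence, and the node itself uniform between
#' `node_min_age` and the last divergence.
#'
#' @param outgroup_ages numeric, outgroup first appearances in Ma, ordered
#'   old to young (most distant outgroup first).
#' @param node_min_age minimum age of the node (oldest descendant tip FAD).
#' @param t_max hard maximum age (Ma).
#' @param grid_resolution number of grid points on `[node_min_age, t_max]`.
#' @return object of class `hedman_posterior`: list with `ages` (grid, Ma),
#'   `prob` (probability mass per grid point, sums to 1) and `mean`.
#' @examples
#' h <- hedman_node_age(300, node_min_age = 280, t_max = 300)
#' h$mean  # 290: uniform on [280, 300]
#' @export
hedman_node_age <- function(outgroup_ages, node_min_age, t_max,
                            grid_resolution = 1000) {
  if (t_max < node_min_age) stop("t_max is younger than node_min_age")
  if (any(!is.finite(outgroup_ages))) stop("outgroup ages must be finite")
  if (t_max == node_min_age)
    return(structure(list(ages = node_min_age, prob = 1,
                          mean = node_min_age),
                     class = "hedman_posterior"))
  if (grid_resolution < 100) stop("grid_resolution must be >= 100")
  g <- seq(node_min_age, t_max, length.out = grid_resolution)
  lo_index <- function(age) {
    age <- min(max(age, node_min_age), t_max)
    which(g >= age - 1e-12)[1L]
  }
  suffix_div <- function(p, lo) {
    # propagate: next value uniform over grid points [lo, m] given mass p[m]
    q <- p
    idx <- seq_along(p)
    q[idx < lo] <- 0
    q[idx >= lo] <- q[idx >= lo] / (idx[idx >= lo] - lo + 1)
    out <- rev(cumsum(rev(q)))
    out[idx < lo] <- 0
    out
  }
  ages <- sort(outgroup_ages, decreasing = TRUE)   # oldest first
  lo1 <- lo_index(ages[1L])
  p <- numeric(grid_resolution)
  p[lo1:grid_resolution] <- 1 / (grid_resolution - lo1 + 1)
  for (a in ages[-1L]) p <- suffix_div(p, lo_index(a))
  p <- suffix_div(p, 1L)                           # node: uniform from min age
  p <- p / sum(p)
  structure(list(ages = g, prob = p, mean = sum(g * p)),
            class = "hedman_posterior")
}

#' @export
print.hedman_posterior <- function(x, ...) {
  cat(sprintf("Node-age posterior on [%.2f, %.2f] Ma; mean %.2f Ma\n",
              min(x$ages), max(x$ages), x$mean))
  invisible(x)
}

# One joint draw of the uniform divergence cascade, vectorised over draws:
# bounds `lb` (low, per outgroup, oldest first) under upper bounds `ub`.
sample_cascade <- function(n, lbs, node_min, ub) {
  cur <- ub
  for (lb in lbs) {
    lo <- pmin(pmax(lb, node_min), cur)
    cur <- stats::runif(n, lo, cur)
  }
  stats::runif(n, pmin(node_min, cur), cur)
}

#' Time-calibrate a tree from outgroup ages
#'
#' Applies the Hedman uniform-divergence model across a whole phylogeny.
#' Node ages are drawn jointly from the root toward the tips: the root age
#' is drawn given the user-supplied external outgroup ages and the hard
#' maximum `root_max`; each internal node is then drawn given its parent's
#' drawn age as upper bound, with the first appearances of successively
#' more rootward sister lineages (filtered to a stratigraphically
#' consistent, nearest-first sequence) plus the external outgroups acting
#' as its outgroup ages. Tips sit at their taxon's first appearance datum.
#' The returned tree is dated with per-node mean ages.
#'
#' @param tree rooted binary `phylo`; tip labels must appear in `taxa`.
#' @param taxa a [taxon_records()] table giving tip FADs.
#' @param outgroups data.frame with columns `name` and `age` (Ma), ordered
#'   from the closest outgroup to the most distant; ages must be
#'   non-decreasing in that order.
#' @param root_max hard maximum root age (Ma).
#' @param n_draws number of joint age draws.
#' @param seed optional integer seed.
#' @return list of class `calibrated_tree`: `tree` (dated `phylo` with
#'   branch lengths in Myr and `root.time` in Ma), `node_ages` (mean age per
#'   internal node, Ma), `draws` (matrix, draws x internal nodes).
#' @export
calibrate_tree <- function(tree, taxa, outgroups, root_max, n_draws = 1000,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  idx <- match(tree$tip.label, taxa$name)
  if (anyNA(idx))
    stop("tips missing from taxon table: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  tip_age <- taxa$fad[idx]
  og_age <- as.numeric(outgroups$age)
  if (length(og_age) >= 2 && any(diff(og_age) < 0)) {
    k <- which(diff(og_age) < 0)[1L]
    stop("outgroups not stratigraphically consistent: ",
         outgroups$name[k + 1L], " (", og_age[k + 1L], " Ma) is younger ",
         "than the closer outgroup ", outgroups$name[k], " (", og_age[k],
         " Ma)")
  }
  nnode <- tree$Nnode
  root <- ntip + 1L
  edge <- tree$edge
  parent_of <- integer(ntip + nnode)
  parent_of[edge[, 2L]] <- edge[, 1L]
  # oldest descendant tip FAD per node
  po <- ape::reorder.phylo(tree, "postorder")
  min_age <- numeric(ntip + nnode)
  min_age[seq_len(ntip)] <- tip_age
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    min_age[p] <- max(min_age[p], min_age[ch])
  }
  if (root_max < min_age[root])
    stop("root_max (", root_max, ") is younger than the oldest tip FAD (",
         min_age[root], ")")
  # sister-lineage outgroup age sequence per node, nearest first, filtered
  # to a non-decreasing (stratigraphically consistent) subsequence
  node_outgroups <- vector("list", nnode)
  for (nd in root + seq_len(nnode) - 1L) {
    ages <- numeric(0)
    cur <- nd
    while (cur != root) {
      par <- parent_of[cur]
      sibs <- setdiff(edge[edge[, 1L] == par, 2L], cur)
      ages <- c(ages, max(min_age[sibs]))
      cur <- par
    }
    ages <- c(ages, og_age)
    keep <- numeric(0); cur_max <- -Inf
    for (a in ages) if (a >= cur_max) { keep <- c(keep, a); cur_max <- a }
    node_outgroups[[nd - ntip]] <- rev(keep)    # oldest first for the cascade
  }
  draws <- matrix(NA_real_, n_draws, nnode)
  colnames(draws) <- as.character(root + seq_len(nnode) - 1L)
  # preorder over internal nodes (root first)
  pre <- unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1L])
  draws[, 1L] <- sample_cascade(n_draws, node_outgroups[[1L]],
                                min_age[root], rep(root_max, n_draws))
  for (nd in setdiff(pre, root)) {
    ub <- draws[, as.character(parent_of[nd])]
    draws[, nd - ntip] <- sample_cascade(n_draws, node_outgroups[[nd - ntip]],
                                         min_age[nd], ub)
  }
  mean_age <- colMeans(draws)
  # enforce stratigraphic consistency of the mean-age tree (each draw is
  # consistent so means already are; clamp defensively for rounding)
  age_all <- c(tip_age, mean_age)
  for (nd in setdiff(pre, root))
    age_all[nd] <- min(age_all[nd], age_all[parent_of[nd]])
  out <- tree
  out$edge.length <- unname(age_all[edge[, 1L]] - age_all[edge[, 2L]])
  out$root.time <- unname(age_all[root])
  structure(list(tree = out, node_ages = age_all[root:(ntip + nnode)],
                 draws = draws),
            class = "calibrated_tree")
}

#' Node and tip ages of a dated tree
#'
#' @param tree a `phylo` with branch lengths in Myr and `root.time` (root age
#'   in Ma).
#' @return numeric vector of ages (Ma) for nodes `1..Ntip+Nnode`.
#' @export
node_ages <- function(tree) {
  if (is.null(tree$root.time)) stop("tree has no root.time; not a dated tree")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntot <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(ntot)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge)))
    depth[tr$edge[k, 2L]] <- depth[tr$edge[k, 1L]] + tr$edge.length[k]
  tree$root.time - depth
}

# ICS chronostratigraphic stage boundaries (Ma), Gzhelian-Changhsingian.
ICS_STAGES <- data.frame(
  stage = c("Gzhelian", "Asselian", "Sakmarian", "Artinskian", "Kungurian",
            "Roadian", "Wordian", "Capitanian", "Wuchiapingian",
            "Changhsingian"),
  start = c(303.7, 298.9, 293.52, 290.1, 283.5, 273.01, 266.9, 264.28,
            259.51, 254.14),
  end = c(298.9, 293.52, 290.1, 283.5, 273.01, 266.9, 264.28, 259.51,
          254.14, 251.902),
  stringsAsFactors = FALSE)
attr(ICS_STAGES, "chart_version") <- "ICS 2023/06"

#' Packaged ICS stage boundary table
#'
#' Stage boundary ages (Ma) for the Gzhelian through Changhsingian interval;
#' the chart version is recorded in the `chart_version` attribute.
#' @return data.frame with columns `stage`, `start`, `end`.
#' @export
ics_stages <- function() ICS_STAGES

#' Construct a stratigraphic time-bin set
#'
#' Two standard binning schemes for Permo-Carboniferous amniote clades: five
#' coarse bins of roughly equal length (Asselian-Sakmarian, Artinskian,
#' Kungurian, Guadalupian, Lopingian), or stage-level bins from the Gzhelian
#' through the Changhsingian (10 bins).
#'
#' @param spec `"five"` or `"stages"`, or a data.frame with columns `name`,
#'   `start`, `end` for custom bins.
#' @param chart stage table as returned by [ics_stages()].
#' @return object of class `time_bins`: data.frame with `name`, `start`,
#'   `end` (Ma), ordered old to young, non-overlapping, `start > end`.
#' @export
make_bins <- function(spec = c("five", "stages"), chart = ics_stages()) {
  if (is.data.frame(spec)) return(time_bins(spec$name, spec$start, spec$end))
  spec <- match.arg(spec)
  stage_bounds <- function(from, to) {
    i <- match(from, chart$stage); j <- match(to, chart$stage)
    if (anyNA(c(i, j))) stop("unknown stage name: ",
                             paste(c(from, to)[is.na(c(i, j))], collapse = ", "))
    c(chart$start[i], chart$end[j])
  }
  if (spec == "five") {
    b1 <- stage_bounds("Asselian", "Sakmarian")
    b2 <- stage_bounds("Artinskian", "Artinskian")
    b3 <- stage_bounds("Kungurian", "Kungurian")
    b4 <- stage_bounds("Roadian", "Capitanian")     # Guadalupian epoch
    b5 <- stage_bounds("Wuchiapingian", "Changhsingian")  # Lopingian epoch
    time_bins(c("Asselian-Sakmarian", "Artinskian", "Kungurian",
                "Guadalupian", "Lopingian"),
              c(b1[1], b2[1], b3[1], b4[1], b5[1]),
              c(b1[2], b2[2], b3[2], b4[2], b5[2]))
  } else {
    time_bins(chart$stage, chart$start, chart$end)
  }
}

#' @rdname make_bins
#' @param name,start,end bin names and bounding ages (Ma, `start > end`).
#' @export
time_bins <- function(name, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start <= end)) stop("each bin must have start > end (Ma)")
  ord <- order(start, decreasing = TRUE)
  name <- name[ord]; start <- start[ord]; end <- end[ord]
  if (length(start) > 1 && any(end[-length(end)] < start[-1] - 1e-9))
    stop("bins overlap")
  structure(data.frame(name = as.character(name), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("time_bins", "data.frame"))
}
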