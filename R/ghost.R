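# Ghost-lineage correction: unsampled lineages implied by a dated phylogeny
# contribute pseudo-taxa to a bin's score set, with morphology imputed under
# Brownian motion.

# Replace non-positive branch lengths by a small positive constant so that
# BM machinery (ancestral states, contrasts) is defined; reported once.
ensure_positive_lengths <- function(tree, eps = 1e-4) {
  bad <- tree$edge.length <= 0
  if (any(bad)) {
    message(sum(bad), " zero-length branch(es) perturbed by +", eps, " Myr")
    tree$edge.length[bad] <- eps
  }
  tree
}

#' Node-value matrix under Brownian motion
#'
#' Tip scores combined with maximum-likelihood (GLS) ancestral estimates at
#' the internal nodes, each axis treated as an independent Brownian motion.
#'
#' @param tree dated `phylo` with positive branch lengths.
#' @param scores score matrix covering all tips.
#' @return matrix with one row per node (`1..Ntip+Nnode`), one column per
#'   axis.
#' @export
node_value_matrix <- function(tree, scores) {
  s <- member_scores(scores, tree$tip.label)
  ntip <- ape::Ntip(tree)
  vals <- matrix(NA_real_, ntip + tree$Nnode, ncol(s))
  vals[seq_len(ntip), ] <- s
  for (j in seq_len(ncol(s))) {
    x <- stats::setNames(s[, j], tree$tip.label)
    vals[ntip + seq_len(tree$Nnode), j] <- phytools::fastAnc(tree, x)
  }
  colnames(vals) <- colnames(s)
  vals
}

# Edges whose time span covers `age` (parent strictly older, child at or
# younger than `age`).
edges_spanning <- function(tree, ages, age) {
  which(ages[tree$edge[, 1L]] > age & ages[tree$edge[, 2L]] <= age)
}

#' Ghost-lineage-augmented per-bin score sets
#'
#' For each time bin, every branch of the dated tree that spans the bin
#' midpoint without representing a taxon sampled in that bin contributes a
#' pseudo-taxon. Its scores are estimated under Brownian motion: ancestral
#' axis values are reconstructed at the internal nodes by maximum likelihood
#' (each axis independently), and the pseudo-taxon takes the linear
#' interpolation in time between the branch's parent and child values at the
#' bin midpoint. Pseudo-taxa are flagged by a `ghost:` rowname prefix and
#' are never counted as sampled diversity.
#'
#' @param dated_tree a dated `phylo` (branch lengths in Myr, `root.time`).
#' @param scores an [`ordination`][pca_ordination] or score matrix covering
#'   all tips.
#' @param bins a [time_bins()] set.
#' @param taxa a [taxon_records()] table (for sampled bin membership).
#' @param axes axis selection passed to the score matrix (default all).
#' @return a `bin_scores` list: per bin, the sampled members' scores plus
#'   interpolated pseudo-taxon rows.
#' @export
ghost_lineage_scores <- function(dated_tree, scores, bins, taxa,
                                 axes = NULL) {
  if (is.null(dated_tree$root.time) || is.null(dated_tree$edge.length))
    stop("tree is undated: needs branch lengths and root.time")
  tree <- ensure_positive_lengths(dated_tree)
  ages <- node_ages(tree)
  vals <- node_value_matrix(tree, member_scores(scores, NULL, axes))
  ntip <- ape::Ntip(tree)
  membership <- suppressWarnings(assign_bins(taxa, bins))
  out <- lapply(seq_len(nrow(bins)), function(i) {
    mid <- (bins$start[i] + bins$end[i]) / 2
    mem <- intersect(membership[[i]], rownames(member_scores(scores)))
    sampled <- member_scores(scores, mem, axes)
    ghost_rows <- list()
    for (k in edges_spanning(tree, ages, mid)) {
      u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
      if (v <= ntip && tree$tip.label[v] %in% mem) next   # sampled lineage
      span <- ages[u] - ages[v]
      w <- if (span > 0) (mid - ages[v]) / span else 0.5
      ghost_rows[[paste0("ghost:", u, "-", v)]] <-
        vals[v, ] + w * (vals[u, ] - vals[v, ])
    }
    if (length(ghost_rows)) {
      g <- do.call(rbind, ghost_rows)
      colnames(g) <- colnames(sampled)
      rbind(sampled, g)
    } else sampled
  })
  names(out) <- bins$name
  structure(out, class = "bin_scores")
}

#' Phylogenetic diversity per time bin
#'
#' Lineage count per bin: the number of sampled member taxa (stratigraphic
#' range overlapping the bin) plus the unsampled (ghost) lineages whose
#' branches span the bin midpoint, plus the clade's single stem lineage for
#' midpoints older than the root. By construction the counts are never
#' below the raw taxic counts.
#'
#' @inheritParams ghost_lineage_scores
#' @return data.frame with columns `bin`, `n_sampled`, `n_ghost`, `n_total`.
#' @export
phylogenetic_diversity <- function(dated_tree, bins, taxa) {
  if (is.null(dated_tree$root.time) || is.null(dated_tree$edge.length))
    stop("tree is undated: needs branch lengths and root.time")
  ages <- node_ages(dated_tree)
  ntip <- ape::Ntip(dated_tree)
  root_age <- dated_tree$root.time
  membership <- suppressWarnings(assign_bins(taxa, bins))
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    mid <- (bins$start[i] + bins$end[i]) / 2
    mem <- membership[[i]]
    ghosts <- 0L
    for (k in edges_spanning(dated_tree, ages, mid)) {
      v <- dated_tree$edge[k, 2L]
      if (v <= ntip && dated_tree$tip.label[v] %in% mem) next
      ghosts <- ghosts + 1L
    }
    if (mid > root_age) ghosts <- ghosts + 1L       # stem lineage
    data.frame(bin = bins$name[i], n_sampled = length(mem),
               n_ghost = ghosts, n_total = length(mem) + ghosts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Raw (taxic) diversity per time bin
#'
#' @inheritParams phylogenetic_diversity
#' @return data.frame with columns `bin` and `n`.
#' @export
taxic_diversity <- function(taxa, bins) {
  membership <- suppressWarnings(assign_bins(taxa, bins))
  data.frame(bin = bins$name, n = lengths(membership),
             row.names = NULL, stringsAsFactors = FALSE)
}
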