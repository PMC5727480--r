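# End-to-end orchestration: search -> calibration -> ordinations -> raw and
# ghost-corrected disparity -> CGS -> diversity -> diet counts -> contrast
# correlations, with a reproducible manifest.

#' Build a pipeline configuration
#'
#' Collects inputs and settings for [run_pipeline()]. Inputs are in-memory
#' objects (readers in this package turn files into them). All stochastic
#' stages draw from the single `seed`.
#'
#' @param discrete a [discrete_matrix()] (including the outgroup taxon).
#' @param continuous a [continuous_matrix()], or `NULL`.
#' @param taxa a [taxon_records()] table for the ingroup taxa.
#' @param outgroup taxon name used to root the parsimony search; dropped
#'   before disparity analyses.
#' @param calibration_outgroups data.frame (`name`, `age`) of external
#'   outgroup ages for node dating, closest first.
#' @param root_max hard maximum root age (Ma).
#' @param bins_raw,bins_ghost bin specifications for the raw and
#'   ghost-corrected analyses (see [make_bins()]).
#' @param tree optional pre-computed tree (skips the parsimony search).
#' @param search_replicates,swap heuristic-search settings.
#' @param n_draws calibration draws.
#' @param n_boot bootstrap replicates for disparity CIs and CGS tests.
#' @param k_axes number of axis pairs for contrast correlations (`NULL`:
#'   all shared positive-variance axes).
#' @param seed integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(discrete, continuous, taxa, outgroup,
                            calibration_outgroups, root_max,
                            bins_raw = "five", bins_ghost = "stages",
                            tree = NULL, search_replicates = 10,
                            swap = "spr", n_draws = 500, n_boot = 500,
                            k_axes = NULL, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full diversity/disparity pipeline
#'
#' Executes, in order: parsimony search (unless a tree is supplied),
#' Hedman-style time calibration, the continuous (log-ratio PCA) and
#' discrete (MORD PCoA) ordinations, raw and ghost-corrected
#' disparity-through-time profiles for both metrics and both character
#' types (eight curves), CGS clade-shape tests for all eight, taxic and
#' phylogenetic diversity, diet counts, and contrast correlations between
#' the two morphospaces. Each stage is wrapped so failures name the stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory: results are written as CSV/JSON/newick
#'   with an md5 manifest.
#' @return list of class `pipeline_result`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  tree <- config$tree
  search <- NULL
  if (is.null(tree)) {
    search <- stage("search", heuristic_search(
      config$discrete, config$continuous, outgroup = config$outgroup,
      n_replicates = config$search_replicates, swap = config$swap))
    tree <- search$trees[[1L]]
  }
  ingroup_tree <- stage("root", {
    tr <- if (config$outgroup %in% tree$tip.label)
      ape::drop.tip(tree, config$outgroup) else tree
    tr
  })

  calib <- stage("calibrate", calibrate_tree(
    ingroup_tree, config$taxa, config$calibration_outgroups,
    root_max = config$root_max, n_draws = config$n_draws))
  dated <- calib$tree

  ingroup <- ingroup_tree$tip.label
  pca <- stage("pca", {
    cm <- member_scores(unclass(config$continuous), ingroup)
    pca_ordination(mean_impute(logratio_transform(continuous_matrix(cm))))
  })
  pcoa <- stage("pcoa", {
    keep <- match(ingroup, config$discrete$taxa)
    dm <- discrete_matrix(config$discrete$states[keep, , drop = FALSE],
                          taxa = ingroup,
                          ordering = config$discrete$ordering)
    pcoa_ordination(suppressWarnings(mord(dm)))
  })

  bins_raw <- make_bins(config$bins_raw)
  bins_ghost <- make_bins(config$bins_ghost)
  membership <- stage("bins", suppressWarnings(
    assign_bins(config$taxa, bins_raw)))

  tracks <- list(pca = pca, pcoa = pcoa)
  profiles <- list(); cgs_results <- list()
  for (tk in names(tracks)) {
    raw_bs <- bin_scores(tracks[[tk]], membership)
    ghost_bs <- stage("ghost", ghost_lineage_scores(
      dated, tracks[[tk]], bins_ghost, config$taxa))
    for (metric in c("sov", "sor")) {
      for (mode in c("raw", "ghost")) {
        bs <- if (mode == "raw") raw_bs else ghost_bs
        bb <- if (mode == "raw") bins_raw else bins_ghost
        key <- paste(tk, metric, mode, sep = "_")
        profiles[[key]] <- disparity_profile(bs, metric,
                                             n_boot = config$n_boot)
        cgs_results[[key]] <- tryCatch(
          cgs_bootstrap(bs, bb, metric, n_boot = config$n_boot),
          error = function(e) NULL)
      }
    }
  }

  diversity <- stage("diversity", list(
    taxic = taxic_diversity(config$taxa, bins_raw),
    phylogenetic = phylogenetic_diversity(dated, bins_ghost, config$taxa)))
  diets <- stage("diets", diet_counts(config$taxa, bins_raw))

  k <- config$k_axes
  if (is.null(k)) k <- min(pca$n_positive, pcoa$n_positive)
  correlations <- stage("contrasts", axis_correlations(
    pca, pcoa, dated, k = k))

  result <- structure(
    list(search = search, tree = ingroup_tree, calibration = calib,
         pca = pca, pcoa = pcoa, bins_raw = bins_raw,
         bins_ghost = bins_ghost, profiles = profiles, cgs = cgs_results,
         diversity = diversity, diet_counts = diets,
         correlations = correlations, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Diversity/disparity pipeline:", length(x$profiles),
      "disparity curves over", nrow(x$bins_raw), "+", nrow(x$bins_ghost),
      "bins;", ape::Ntip(x$tree), "ingroup taxa\n")
  for (nm in names(x$cgs))
    if (!is.null(x$cgs[[nm]]))
      cat(sprintf("  CGS %-14s %.3f (null %.3f, p = %.3f)\n", nm,
                  x$cgs[[nm]]$cgs, x$cgs[[nm]]$null, x$cgs[[nm]]$p_value))
  invisible(x)
}

# Serialize results + config and an md5 manifest into out_dir.
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1]] <<- p
  }
  write_newick(result$calibration$tree, file.path(out_dir, "dated_tree.nwk"))
  paths <- c(paths, file.path(out_dir, "dated_tree.nwk"))
  for (nm in names(result$profiles)) wcsv(result$profiles[[nm]],
                                          paste0("profile_", nm, ".csv"))
  wcsv(result$diversity$taxic, "diversity_taxic.csv")
  wcsv(result$diversity$phylogenetic, "diversity_phylogenetic.csv")
  wcsv(result$diet_counts, "diet_counts.csv")
  wcsv(result$correlations, "axis_correlations.csv")
  wcsv(data.frame(taxon = result$pca$taxa, result$pca$scores),
       "pca_scores.csv")
  wcsv(data.frame(taxon = result$pcoa$taxa, result$pcoa$scores),
       "pcoa_scores.csv")
  cg <- lapply(result$cgs, function(x)
    if (is.null(x)) NULL else list(cgs = x$cgs, null = x$null,
                                   p_value = x$p_value))
  jsonlite::write_json(cg, file.path(out_dir, "cgs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, file.path(out_dir, "cgs.json"))
  cfg <- result$config
  cfg_small <- cfg[setdiff(names(cfg), c("discrete", "continuous", "taxa",
                                         "tree", "calibration_outgroups"))]
  jsonlite::write_json(cfg_small, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  paths <- c(paths, file.path(out_dir, "config.json"))
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
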