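Package: dispartime
Title: Diversity and Disparity of Fossil Clades Through Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing taxic diversity and morphological disparity
    through the evolutionary history of fossil clades, using both discrete
    cladistic characters and continuous morphometric ratios. Provides readers
    for NEXUS and TNT character matrices, Fitch and Farris (additive) parsimony
    tree lengths with ensemble fit indices, heuristic tree search and
    symmetric-resampling node support, Hedman-style Bayesian node-age
    calibration from stratigraphically consistent outgroups, maximum observable
    rescaled distance (MORD) with principal coordinate analysis, log-ratio
    principal component analysis, time-binned disparity (sum of variances, sum
    of ranges) with taxon bootstrapping, ghost-lineage imputation under
    Brownian motion, scaled centre-of-gravity clade-shape statistics,
    phylogenetic independent contrast correlations between morphospaces, and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phytools,
    jsonlite,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
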