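# dispartime

Tools for asking a classic macroevolutionary question of a fossil clade: do
taxic diversity (how many species) and morphological disparity (how much of
morphospace they occupy) rise and fall together through the clade's history,
and is disparity concentrated early (a "bottom-heavy" clade), late
("top-heavy"), or in the middle? The package targets the kind of dataset a
vertebrate palaeontologist typically has — a cladistic matrix of discrete
characters, a table of continuous morphometric ratios, stratigraphic ranges
and diet assignments per taxon — and runs the two character types through
parallel, directly comparable analysis tracks.

It is aimed at palaeobiologists doing disparity-through-time studies on
Permo-Carboniferous tetrapods and similar fossil clades, but nothing in the
machinery is clade-specific.

## What it computes

**Parsimony.** Tree length for unordered discrete characters (Fitch) and
continuous characters treated as additive (Farris interval algorithm), a
heuristic search (random addition sequences + NNI/SPR swapping) over the
combined length, ensemble fit indices on a tree

    CI = Σmᵢ / Σsᵢ,   HI = 1 − CI,   RI = (Σgᵢ − Σsᵢ) / (Σgᵢ − Σmᵢ)

(sᵢ observed, mᵢ minimum, gᵢ maximum steps of character *i*), and
symmetric-resampling node support (each character's weight doubled or halved
with probability *p*/2 per replicate).

**Time calibration.** Hedman's outgroup-based Bayesian node dating: with
successive outgroup first appearances `o₁ ≥ o₂ ≥ … ≥ oₖ` and a hard maximum
`t_max`, each divergence is uniform between its outgroup's age and the
previous divergence, and the node is uniform between its oldest descendant
tip and the last divergence. Applied root-to-tips over the whole tree, with
the mean of the joint draws dating each node.

**Morphospaces.** Continuous track: log-ratio transform → mean-value
imputation → PCA on the covariance matrix. Discrete track: maximum
observable rescaled distance,

    MORD(x, y) = Σⱼ dⱼ(x, y) / Σⱼ maxdⱼ   over mutually scored characters j,

followed by principal coordinate analysis without negative-eigenvalue
correction, so the count of positive-variance axes is meaningful.

**Disparity through time.** Sum of variances and sum of ranges per time bin
on either score set, taxon-bootstrap confidence intervals, ghost-lineage
correction (unsampled branches crossing a bin midpoint contribute
pseudo-taxa whose scores are interpolated along the branch between
Brownian-motion ML ancestral estimates), taxic and phylogenetic diversity,
diet contingency tables and convex-hull occupation/overlap.

**Clade shape.** The scaled centre of gravity of a disparity profile,

    CG = Σ dᵢ tᵢ / Σ dᵢ,  tᵢ = bin midpoint on the [0, 1] clade time axis,

with the flat-profile CG as the null expectation (it differs from 0.5 when
bins are unequal) and a two-tailed taxon-bootstrap test of the deviation.

**Synthetic data.** A birth–death generator (extinct tips retained) with
Brownian-motion ratios, Mk discrete characters with planted missing data and
polymorphism, Poisson-sampled stratigraphic ranges, and diets assigned
deterministically from the traits — every downstream method is testable
against recorded ground truth.

## Worked example

```r
library(dispartime)

ds <- simulate_dataset(n_taxa = 20, seed = 11)
#> Synthetic fossil-clade dataset: 20 taxa, 75 discrete + 31 continuous characters (seed 11)

pc <- pca_ordination(mean_impute(logratio_transform(ds$continuous)))
#> PCA ordination: 20 taxa, 20 axes ( 19 with positive variance )
po <- pcoa_ordination(mord(ds$discrete))
#> PCoA ordination: 20 taxa, 10 axes ( 10 with positive variance )

cal <- calibrate_tree(ds$tree, ds$taxa,
                      outgroups = data.frame(name = c("og_near", "og_far"),
                                             age = c(305, 310)),
                      root_max = 325, n_draws = 1000, seed = 11)
round(cal$tree$root.time, 2)
#> 303.31

bins <- make_bins("stages")
gb <- ghost_lineage_scores(cal$tree, pc, bins, ds$taxa)
disparity_profile(gb, metric = "sov")[, c("bin", "n", "n_ghost", "value")]
#>              bin n n_ghost      value
#> 1       Gzhelian 2       2 0.06595808
#> 2       Asselian 2       2 0.82508673
#> 3      Sakmarian 2       2 0.31860323
#> 4     Artinskian 4       4 1.75035478
#> 5      Kungurian 6       3 2.97844068
#> 6        Roadian 7       4 5.24149793
#> 7        Wordian 4       3 6.87879752
#> 8     Capitanian 5       3 6.94940378
#> 9  Wuchiapingian 2       1 2.65533937
#> 10 Changhsingian 1       0         NA

cgs_bootstrap(gb, bins, metric = "sov", n_boot = 1000, seed = 11)
#> CGS = 0.7072 (flat-profile null = 0.5037), bootstrap p = 0.000 (n = 1000)
```

Reading the output: each row is a geological stage; `n` is the number of
score rows used in that bin (`n_ghost` of them inferred ghost lineages),
`value` the sum of variances over all positive-variance axes. Disparity for
this particular simulated clade builds toward the Capitanian, and its centre
of gravity (0.707, against a flat-profile null of 0.504) marks it as
significantly top-heavy.

`run_pipeline(pipeline_config(...))` chains all of the above — search,
calibration, both ordinations, the eight disparity curves (2 metrics × 2
character types × raw/ghost), CGS for each, diversity, diet counts and
contrast correlations — and can write every table with an md5 manifest for
reproducibility.

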