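---
title: "Methods: diversity and disparity of fossil clades through time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity and disparity of fossil clades through time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices behind
`dispartime`, in the order the pipeline runs them. The package implements a
complete disparity-through-time workflow for fossil clades scored with both
discrete cladistic characters and continuous morphometric ratios; its goal
is that the two character types can be carried through strictly parallel
tracks and compared on equal terms.

## Parsimony

Discrete characters are unordered and optimised with Fitch parsimony. A
polymorphic cell contributes its whole state set at the tip (ambiguity
semantics: the tip may realise any of its states), and a missing cell
contributes the union of states observed for that character, so it can
never force a step. Continuous characters are treated as additive: the
per-character length is the minimal sum of absolute parent–child
differences over internal assignments, computed with the Farris interval
algorithm. Both lengths are invariant to root placement, and both are
vectorised across characters, so a tree evaluation costs one pass over the
nodes.

The heuristic search uses random addition sequences followed by
hill-climbing branch swapping (SPR by default, NNI available), over the
combined discrete + continuous length with the continuous characters
weighted one step per unit of raw ratio difference, the convention of
mixed-matrix parsimony programs. All distinct topologies tied at the best
length are retained (first-found order breaks ties deterministically), and
trees that differ only in the resolution of branches whose minimum length
over all most-parsimonious reconstructions is zero are condensed before
counting. That minimum is computed from the Fitch/Wagner final (MPR) state
sets; the one subtlety is that a rooted binary tree's two root edges are
halves of a single unrooted edge, whose minimum change must be read from
the preliminary sets of the two root children — treating the halves
independently would collapse genuinely supported splits.

Fit indices are reported for the discrete partition: `CI = Σm/Σs`,
`HI = 1 − CI`, `RI = (Σg − Σs)/(Σg − Σm)`. Minimum steps `m` count one less
than the number of states observed in unambiguous cells; a state that only
ever occurs inside polymorphic sets need never be realised, so it cannot
force a step — counting it would break `m ≤ s` under the ambiguity
semantics above. Maximum steps `g` for an unordered character are the
number of scored tips minus the largest single-state count, polymorphic
tips counting toward their most favourable state. `RI` is undefined (and
flagged) when `Σg = Σm`, e.g. for constant matrices.

Symmetric resampling perturbs each character's weight — doubled with
probability `p/2`, halved with probability `p/2`, default `p = 1/3` — and
reruns a reduced search (one addition sequence, NNI) per replicate; a node
is scored by the fraction of replicates whose strict consensus of best
trees retains its bipartition. The reduced per-replicate effort is the
usual economy for resampling support and is a parameter, not a constant.

## Time calibration

Node ages come from the outgroup-based Bayesian approach in which, given
successively more distant outgroups with first appearances
`o₁ ≥ o₂ ≥ … ≥ oₖ` and a hard maximum `t_max`, the deepest divergence is
uniform on `[o₁, t_max]`, each later divergence uniform between its
outgroup's age and the previous divergence, and the node uniform between
its oldest descendant tip and the last divergence. `hedman_node_age()`
computes the marginal posterior by propagating this cascade on a uniform
age grid (default 1000 points), which makes convergence directly testable:
doubling the grid moves the mean by well under 0.1 Myr in the tested
configurations. Whole-tree calibration (`calibrate_tree()`) needs joint
draws rather than marginals, and samples the same cascade forward — the
generative process is identical, so no separate approximation is
introduced — root first (bounded by the user's root maximum), then each
node bounded by its parent's drawn age, with sister-lineage oldest first
appearances (filtered to a stratigraphically consistent nearest-first
sequence) plus the external outgroups as that node's outgroup ages. Tips
sit at their first appearance datum; last appearances matter only for bin
membership. The reported tree uses per-node mean ages, which inherit
stratigraphic consistency from the draws because every draw is consistent
pointwise.

Stage boundaries are packaged as a versioned constant table (ICS 2023/06)
covering the Gzhelian through the Changhsingian; the five coarse bins
(Asselian–Sakmarian, Artinskian, Kungurian, Guadalupian, Lopingian) are
built from it.

## Morphospaces

The continuous characters are ratios, so they are logged before
ordination; the default is an elementwise natural log, since the variables
are already ratios and the purpose is to remove the spurious correlation
structure of raw ratios. A centred log-ratio variant (row-centring after
the log) is exposed as an option; base and centring do not change the
downstream disparity trends, only the absolute eigenvalues. Missing values
are mean-imputed per character (leaving character means untouched), and PCA
is run on the covariance matrix — after the log transform the variables
are commensurable, and variance-based PCA keeps the axis variances in
interpretable units.

The discrete characters yield a maximum observable rescaled distance
matrix: per pair, the summed per-character differences divided by the
summed maximum possible differences, both over mutually scored characters.
Unordered characters differ by 1 exactly when their state sets fail to
intersect (so shared polymorphism counts as agreement — exposed as the
documented default); ordered characters use the minimum absolute state
difference rescaled by the character's observed range. Pairs with no
mutually scored characters are data, not errors: they are flagged, and by
default filled with the maximum observed distance (with a warning), with
an `NA`-preserving option for workflows that prefer trimming.

PCoA double-centres `−D²/2` and eigendecomposes. No Cailliez or Lingoes
correction is applied: the analysis downstream counts axes with positive
variance, which only means something on uncorrected eigenvalues.
Eigenvalues within `1e-9` (relative) of zero are treated as numerical
zeros, scores are returned on the positive axes only, and the axis
variances are scaled by `1/(n−1)` so the PCoA of Euclidean distances among
PCA scores reproduces the PCA variances — an invariant the test suite
checks to `1e-8`.

## Disparity, ghost lineages and clade shape

A taxon belongs to every bin its `[FAD, LAD]` range overlaps with positive
length; a zero-length touch (including point occurrences) goes to the
older bin. Sum of variances uses the sample (n−1) variance per axis,
summed over all positive-variance axes by default (a configurable axis
selection); it is undefined, and flagged, below two members. Sum of ranges
is defined from one member up. Confidence intervals are percentile
2.5/97.5 taxon bootstraps within bins.

The ghost-lineage correction evaluates each bin at its midpoint — the only
symmetric choice for a method that infers morphology at a point in time.
Every branch of the dated tree spanning the midpoint that is not the
terminal branch of a taxon sampled in that bin contributes a pseudo-taxon.
Its scores are linear interpolations in time between the branch's
endpoint values, with internal values estimated per axis by maximum
likelihood under Brownian motion; axes are treated independently because
ordination axes are orthogonal by construction. Pseudo-taxa are flagged
(`ghost:` rowname prefix) and never enter raw diversity; both disparity
metrics are augmented identically. Phylogenetic diversity counts sampled
members plus midpoint-crossing unsampled branches, plus the single stem
lineage for midpoints older than the root — defining it this way (rather
than as a bare crossing count) guarantees it can never fall below taxic
diversity, since a taxon's range can overlap a bin without spanning its
midpoint.

The scaled centre of gravity is `CG = Σdᵢtᵢ/Σdᵢ` with `tᵢ` the bin
midpoint rescaled so 0 is the start of the oldest occupied bin and 1 the
end of the youngest. The null expectation is the CG of a flat profile over
the same occupied bins — computed, not assumed to be 0.5, because unequal
bin durations shift it. Significance is a two-tailed percentile test: the
profile and its CG are recomputed under taxon bootstrapping within bins,
and the p-value is twice the smaller tail of the bootstrap distribution
relative to the null. On symmetric synthetic data this test holds its
nominal 5% size within binomial error (checked at 200 replicates in the
acceptance suite).

Zero-length branches (which arise when mean node ages coincide) are
perturbed by +0.0001 Myr, with a message, exactly where Brownian-motion
machinery (ancestral states, contrasts) requires positive lengths.

## Contrast correlations

To compare the two morphospaces, axes are paired positionally (PC1 with
PCo1, and so on), both score vectors are transformed to phylogenetic
independent contrasts on the dated tree, and the Pearson correlation of
the contrasts is computed through the origin — the standard convention,
since contrast signs are arbitrary; a with-intercept variant is exposed as
an option. The absolute correlation is reported alongside the signed one
because ordination axis orientations are arbitrary.

## The synthetic generator

`simulate_dataset()` emulates the shape of a mid-sized Permo-Carboniferous
amniote clade: 30 taxa by default, 75 unordered discrete characters
evolved under an equal-rates Mk model with 30% missing cells and 2%
polymorphic cells planted uniformly at random, 31 strictly positive
continuous ratios evolved as Brownian motion on the log scale
(σ² = 0.01 per Myr), a birth–death tree (0.15/0.12 per Myr) originating at
300 Ma with extinct tips retained, Poisson-sampled stratigraphic ranges at
0.3 occurrences per Myr (with at least one occurrence, so every tip is an
observed taxon), and diets assigned deterministically from the first
continuous trait (lower half carnivore, next 30% omnivore, top 20%
herbivore), so diet structure in morphospace is planted and recoverable.
These defaults were chosen once, to mirror the dimensions and completeness
typical of real captorhinid-grade matrices, and give clades spanning
roughly the Gzhelian–Changhsingian interval that the packaged stage table
covers.

What the generator does not emulate — and therefore what passing tests on
it cannot certify about real data: correlated characters (real cladistic
and morphometric characters are not independent), heterogeneous rates
across lineages or characters, non-random missing data (real missingness
concentrates in poorly preserved taxa and regions of the skeleton),
directional trends, and any particular relationship between diet and
diversification. Tests against it establish that the machinery computes
what it claims under known conditions, not that any empirical clade
behaves like the model.

## Numerical choices and degenerate inputs

* Tree-length ties and equality of disparity values use an absolute
  tolerance of `1e-9`; state comparisons are exact integer bitmask
  operations (up to 30 states per character).
* The Hedman grid is uniform with 1000 points by default (minimum 100
  enforced); a degenerate interval (`t_max` equal to the minimum age)
  short-circuits to a point mass.
* Bins must be non-overlapping and ordered old to young; construction
  sorts and validates.
* Empty bins, singleton bins (for variance), all-zero profiles, all-missing
  characters, and trees without dates all fail fast with specific errors
  rather than propagating `NA`s.
* Problem sizes in the test and acceptance suites (hundreds of fuzzed 4–6
  tip parsimony instances against exhaustive oracles, 150–200 simulation
  replicates for unbiasedness and test-size checks, 14–25 taxon pipeline
  fixtures) were chosen as the smallest sizes at which the checked
  quantities are statistically meaningful.

## Known limitations

* The heuristic search is plain random-addition + NNI/SPR in R: adequate
  for matrices of a few dozen taxa, not for hundreds; there is no implied
  weighting, Bremer support, or TBR.
* Polytomies are scored by sequential Fitch folding, which equals the
  length of one caterpillar resolution (soft-polytomy semantics depend on
  fold order); searches operate on binary trees, so this only affects
  reporting on condensed trees.
* Mean-value imputation and maximum-distance filling of incomparable pairs
  are deliberate, simple conventions matching common practice; both
  flatten structure when missingness is extreme.
* Calibration treats outgroup ages as known constants and does not model
  their sampling uncertainty.
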