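---
title: "Multi-scale cell mapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale cell mapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatmatch)
```

## The mapping model

`spatmatch` matches cells between two spatial samples by solving a linear
assignment problem (LAP): query cells are "workers", reference cells are
"tasks", and the optimal assignment minimizes the summed cost
$C_{ij} = \sum_k (1 - S^{(k)}_{ij})$ over a user-chosen set of similarity
matrices $S^{(k)}$. The matrices are deliberately *not* weighted. Their
ranges differ — Pearson correlations live in $[-1, 1]$ (so one correlation
metric can contribute up to 2 to a pair's cost), Jaccard composition in
$[0, 1]$, the label indicator in $\{0, 1\}$ — and this asymmetry is the
mechanism by which categorical prior knowledge (labels, niche composition)
exerts a sharp discriminative pull without explicit weights. The
`cost_diagnostics()` output makes this visible: the coefficient of
variation of a matrix's cost contribution measures its discriminative
power, and the per-pair proportion of contribution (POC,
$(1-S^{(k)}_{ij})/C_{ij}$, summing to 1 over metrics) measures how much of
a mapped pair's cost each metric explains.

Correlation scores are used raw: we do not rescale Pearson values into
$[0, 1]$, because the cost definition is literally "one minus the
similarity" and a negative correlation genuinely should cost more than an
uncorrelated pair.

### Batching and epochs

Mapping all cells at once would make the LAP cubic in the full sample
size, so cells are drawn into batches of size $B$ (default 1000): both
sets are sampled without replacement so the larger set is partitioned and
every cell appears exactly once per epoch, and the smaller set is padded
by cyclic repetition of a shuffled copy of itself — padded entries are
duplicates of real identifiers, so assignments to them fold back into
many-to-one matches. Across epochs (default 25) batches are redrawn (epoch
$e$ reseeds with `seed + e`) and a query cell's retained pair is replaced
only when the new pair's cost is *strictly* lower; on ties the earlier
epoch's pair is kept. Retained cost per query is therefore non-increasing
in the epoch index, which the test suite audits directly. When a single
batch covers both sets every epoch re-solves the identical problem, so the
loop stops after the first epoch.

Per-batch cost submatrices are sliced from one precomputed full cost
stack rather than recomputed per batch: pairwise scores do not depend on
the batching, so the results are identical and the work is done once.

The assignment itself is a standard primitive; we delegate it to the
Hungarian-family solver in the `clue` package behind the `solve_lap()`
surface, and verify optimality in tests against brute-force enumeration
of all permutations on small instances. Costs are shifted by their minimum
when negative entries occur, which leaves the argmin unchanged.

### Filtering

Two optional query-side filters run before mapping. The score threshold
(default 0.9) keeps a query cell if *any* correlation/Jaccard metric gives
it at least one reference match above the threshold — the "any matrix"
reading, matching the rule that a query needs only one sufficiently good
match somewhere. The label filter drops query cells whose label matches no
reference cell. The label indicator is never thresholded by the score
filter; it has its own filter.

One practical caveat: whether a 0.9 correlation threshold is attainable
depends strongly on sequencing depth. On the shallow synthetic libraries
produced by this package's generator (median library ≈ 1600 counts over
2000 genes), cell–cell Pearson correlations top out near 0.5, and a 0.9
threshold removes every query cell (the filter then errors rather than
silently mapping nothing). The threshold is therefore exposed as a user
option (`threshold = NULL` disables it), and analyses comparing cost
configurations should disable it so all configurations map the identical
query set.

## Signals at three scales

The expression signal defaults to log-normalized counts (per-cell scaling
to the median library size, then `log1p`) restricted to the top 2000
variable genes, ranked by a variance/mean dispersion on the normalized
layer. TF-IDF normalization and PCA embeddings (default 30 components) are
available alternatives; any custom signal can be supplied through
`signal_matrix()`. Similarities are always computed over the feature
intersection of the two samples.

*Niches* are the spatial neighbor sets of each cell: k-nearest neighbors
(default $k = 6$ for the synthetic protocol), all cells within a given
depth on the Delaunay triangulation (the dual of the Voronoi tessellation;
boundary edges longer than the 99th percentile of edge lengths are pruned,
since convex-hull simplices otherwise create spurious long-range
adjacency), or all cells within a radius. The niche signal replaces a
cell's profile with its neighborhood mean. Whether the neighborhood
includes the center cell is not pinned down by the mean-of-neighborhood
definition; we include it by default (`include_center = TRUE`), which
keeps single-cell niches well defined, and expose the flag for the other
reading. Radius niches can be empty; by default that is an error, with an
explicit `fallback_to_cell` escape hatch.

*Territories* are large-scale contiguous domains. The preferred source is
labels provided with the data (e.g. from an upstream image-based
territory-detection pipeline, which is out of scope here). The built-in
fallback — k-means on the PCA embedding followed by splitting each cluster
into its connected components on the Delaunay graph, so no label spans
disconnected regions — is an approximation and documented as such. The
territory signal is the territory-mean profile, so territory similarity is
block-constant over (query territory, reference territory) pairs.

## The synthetic regimes

The generator emulates multi-territory 2-D tissue layouts with known
ground truth. Defaults are the study conditions: 12 samples per regime,
5000 cells and 2000 genes per sample, differential-expression probability
0.5 between territory-scale populations and 0.05 between layers. Cells are
uniform points in the unit square; circular territories draw radius
$\sim U(0.05, 0.2)$ (our choice, recorded here, not claimed as anyone
else's), overlaps resolve in favor of the latest-drawn territory, and the
circle regime redraws its geometry until all five territories are
populated. The "rod" shape is a capsule (a segment with semicircular caps)
of random orientation; the "chaos map" territory is the set of cells within
0.025 of a Clifford-type quadratic attractor scaled into a random sub-box.
Layers are equal-width distance bands (radial for circles, spine-distance
for rods, attractor-distance for the chaos map).

Counts follow a gamma-Poisson: per-gene baseline means are log-normal
(meanlog $\log 0.5$, sdlog 1), dispersion 0.3, and each cell type carries
fold-changes that differ from 1 only at its DE genes, drawn log-normal
(sdlog 0.5). Fold-changes compose hierarchically — a territory-scale fold
(probability 0.5), a layer fold (probability 0.05) and a type-within-layer
fold — and the models are built once per regime, so cells of the same type
are exchangeable across samples (the suite checks the standardized
per-gene mean differences between samples against their sampling band).
These parameters are a documented stand-in for a full single-cell count
simulator: they reproduce negative-binomial marginals and the stated DE
probabilities but not batch effects, dropout structure, or realistic
library-size spread. Consequently, passing tests demonstrate correct
mechanics and the expected *ordering* of configurations (context metrics
improve neighborhood recovery), not absolute performance on real tissue.

Ground-truth spatial context is recorded as "interaction" labels: the
cell-type labels of each cell's $k = 6$ nearest neighbors, sorted
lexicographically and joined with `@` so the label is order-invariant.

## Evaluation and clustering

Mapping quality is scored two ways: the adjusted Rand index between mapped
query and reference cell-type labels (closed-form contingency
implementation, cross-checked in tests against an independent one), and
the per-pair neighborhood Jaccard — the frequency-aware Jaccard between
the k-NN label multisets of the two mapped cells. The frequency-aware
index disambiguates repeats (A, A.1, A.2, ...) before the set operations,
which is algebraically the multiset Jaccard
$\sum_\ell \min(a_\ell, b_\ell) / \sum_\ell \max(a_\ell, b_\ell)$; the
worked case $\{A,A,B\}$ vs $\{A,B,B\} = 0.5$ is frozen in the tests. Two
empty multisets score 1 (identical neighborhoods), a convention that only
matters for radius niches.

*Co-mapping clustering* groups query cells that prefer the same reference
cells: candidates are ranked by ascending cost — the source material
phrases this as sorting costs "in descending order" of preference, which
we read as best-match-first, since lower cost means better — the top
$n = 30$ reference ids form each query's set, pairwise distance is
$1 - J$ (note the companion index formula in the source swaps union and
intersection; we use the standard $|A \cap B| / |A \cup B|$, the only
reading consistent with its stated range), and average-linkage
hierarchical clustering is cut at a count $k$ or height $h$. The distance
is a semimetric: symmetric, zero iff the top sets coincide.

*Sample clustering* uses the samples-by-samples mean mapping cost directly
as a distance: the matrix is asymmetric (query and reference roles
differ), so we symmetrize by averaging the two directions — our choice —
ignore the diagonal, and cut the average-linkage dendrogram at height 0.5
by default. Average linkage is our choice as well; the linkage criterion
was not specified in the source protocol.

Inter-group differential expression is a per-gene two-sided Wilcoxon
rank-sum test on the normalized layer with Benjamini–Hochberg correction
and significance at adjusted $p < 0.05$; `wilcox.test()` switches to the
exact distribution automatically for small untied groups.

## Numerical conventions

* Zero-variance signal columns would make Pearson undefined; they score 0
  (with a warning) instead of propagating NaN.
* Correlations are clamped to $[-1, 1]$ to absorb floating-point
  overshoot; the stack recomputation invariant is checked at $10^{-12}$.
* Variable-feature ties break on gene identifier, making selection
  deterministic.
* Mapped pairs with zero total cost have undefined POC; they are excluded
  from diagnostics with their count reported.
* All randomness (batching, layouts, counts, k-means restarts) is driven
  by explicit integer seeds; per-sample generator sub-seeds are derived
  with fixed multipliers and kept within 32-bit range.

## Problem sizes used in the checks

The acceptance-style checks run the full 12-sample circle regime at
default size (5000 cells, 2000 genes) for the generator contract and event
bookkeeping, and a 3-sample circle regime at 1000 cells for the mapping
protocol (batch 1000, 25 epochs, $k = 6$ niches, 2000 variable genes) —
the configuration-comparison runs use all 6 ordered mapping events and
compare mean neighborhood Jaccard between `"fnc"` and `"f"`. The
epoch-retention audit uses batches of 250 on the 1000-cell pair so batch
composition genuinely varies between epochs; with a full-coverage batch
the check would be vacuous.

## Known limitations

* The territory fallback is a coarse stand-in for image-based territory
  detection; provided labels should be preferred whenever available.
* The generator does not model dropout, batch effects or realistic
  library-size variation, and its shallow libraries depress absolute
  correlation scores (see the threshold caveat above).
* Many-to-many output lists one retained (best) pair per active query
  cell; richer candidate sets are available from the cost stack itself
  (as used by co-mapping clustering).
* Leiden/Louvain community detection on the co-mapping distance is exposed
  through the returned distance matrix rather than wrapped; hierarchical
  clustering is the default route.
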