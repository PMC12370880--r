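# spatmatch

Interpretable, multi-scale mapping of cells across heterogeneous spatial
omics samples.

## The problem

Spatial transcriptomics and spatial proteomics samples taken across
patients, conditions, technologies or time points rarely share tissue
structure, so alignment tools that warp one section onto another cannot be
used. `spatmatch` instead *maps* cells: each query cell is matched to the
reference cell(s) that best resemble it — not only in its own expression,
but in the expression of its spatial neighborhood (niche), its larger
tissue domain (territory), the cell-type composition of its niche, and its
cell-type label.

## The method

Matching is a linear assignment problem (LAP). For query cell *i* and
reference cell *j*, the cost is the unweighted sum of reciprocal
similarity scores over any combination of similarity matrices
S<sup>(k)</sup>:

> C<sub>ij</sub> = Σ<sub>k</sub> (1 − S<sub>ij</sub><sup>(k)</sup>)

with

- **feature (f)** — Pearson correlation of the two cells' expression
  signals (highly variable genes of the normalized counts, or a PCA
  embedding), computed over the feature intersection of the two samples;
- **niche (n)** — the same correlation on neighborhood-mean signals, with
  niches defined by k-nearest neighbors, Delaunay-graph depth (the Voronoi
  dual), or a spatial radius;
- **territory (t)** — the correlation on territory-mean signals, using
  provided domain labels or a built-in k-means + spatial-split fallback;
- **composition (c)** — a frequency-aware Jaccard index between the
  cell-type multisets of the two niches (repeated labels are disambiguated
  A, A.1, A.2, ... before the set operations);
- **label (y)** — a 0/1 indicator of cell-type agreement;
- plus user-supplied custom matrices.

Configurations are written with one-letter codes, e.g. `"fnct"`. Matrices
are never weighted: categorical metrics are sharply discriminative, while
correlation metrics dominate the cost magnitude, and the per-pair
*proportion of contribution* (POC) and per-matrix coefficient of variation
(CV) make each metric's role explicit.

The solver runs in randomized batches (sampling without replacement; the
smaller set is padded by cyclic duplication, which naturally yields
many-to-many matches) across multiple epochs; a query cell's retained pair
is replaced only by a strictly cheaper one. Optional filters drop query
cells with no similarity above a threshold or with no matching label in
the reference. A greedy pass can reduce the result to one-to-one pairs.

The package also ships a synthetic spatial-data generator (five regimes —
circle, layer, dropped, random one/two cell — with gamma-Poisson counts
and k-NN "interaction" ground-truth labels), evaluation metrics (adjusted
Rand index of mapped labels, neighborhood Jaccard), co-mapping clustering
of query cells, and cost-based hierarchical clustering of whole samples.

## Worked example

```r
library(spatmatch)

cfg <- regime_config("circle", n_samples = 2, n_cells = 1000,
                     n_genes = 2000, seed = 42)
samples <- simulate_regime(cfg)
samples[[1]]
#> spatial_dataset 'circle_1': 2000 genes x 1000 cells
#>   tracks: cell_labels, territory_labels, interaction_labels

m <- map_samples(samples[[1]], samples[[2]], metrics = "fnc",
                 batch_size = 1000, epochs = 25, seed = 42,
                 threshold = NULL)
print(m)
#> sample_mapping: circle_1 -> circle_2
#> mapping_result: 1000 pairs [metrics: feature, niche, composition; epochs: 25]
#>   mean total cost: 0.89865
#>     query_barcode     ref_barcode total_cost epoch score_feature score_niche
#> 1 cell_0001_00001 cell_0002_00434  0.7805316     1     0.4134995   0.8059689
#> ...

ev <- evaluate_mapping(m$mapping, samples[[1]], samples[[2]], k = 6)
round(c(ari = ev$ari, mean_ji = ev$mean_jaccard), 3)
#>     ari mean_ji
#>   0.917   0.869

cost_diagnostics(m$stack, m$mapping)
#>        metric         cv   mean_poc n_pairs n_zero_cost
#> 1     feature 0.03616530 0.69310462    1000           0
#> 2       niche 0.08198982 0.22355315    1000           0
#> 3 composition 0.97773923 0.08334222    1000           0
```

The mapping recovers both cell identity (ARI 0.92) and spatial context
(mean neighborhood Jaccard 0.87). The diagnostics show the typical
division of labor: the composition metric is the most discriminative
(highest CV) yet contributes least to the total cost, while feature and
niche correlations carry most of the cost magnitude.

A thin command-line wrapper with `simulate`, `map` and `evaluate`
subcommands is installed at `inst/cli/spatmatch.R`.

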