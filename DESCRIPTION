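Package: spatmatch
Title: Interpretable Multi-Scale Cell Mapping Across Heterogeneous Spatial Omics Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps cells between spatial omics samples that lack structural
    correspondence by solving a batched linear assignment problem. The mapping
    cost is the unweighted sum of reciprocal similarity scores computed at
    several biological scales: single-cell expression, niche (spatial
    neighborhood) expression, tissue-territory expression, niche cell-type
    composition (frequency-aware Jaccard), and cell-type label agreement.
    Includes a synthetic spatial-regime generator with ground-truth labels,
    mapping evaluation metrics (adjusted Rand index, neighborhood Jaccard),
    co-mapping clustering of query cells, and cost-based sample clustering.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    clue,
    deldir,
    RANN,
    igraph,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
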