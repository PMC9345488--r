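Package: hierdr
Title: Hierarchy-Supervised Dimensionality Reduction by Pairwise Distance Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Injects a user-supplied class hierarchy into nonlinear
    dimensionality reduction (t-SNE, UMAP, PHATE) and PCA by scaling each
    pairwise distance with a hierarchical distancing factor derived from
    shortest-path distances between the samples' labels in an undirected
    label graph. Supports known labels, probability-weighted predicted
    labels, and semi-supervised settings where some samples carry no label.
    Includes embedding-quality metrics (a chi-squared neighbourhood score,
    a hierarchically weighted silhouette, convex-hull overlap) with
    Simpson's-rule area-under-curve summaries over strength sweeps, and a
    synthetic generator of labelled point clouds whose class geometry
    tracks the hierarchy to a tunable degree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    Rtsne,
    uwot,
    phateR,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
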