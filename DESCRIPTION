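Package: spatialDG
Title: Spatial Domain Identification with Dual-Graph Contrastive Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies spatial domains in spatially resolved transcriptomics
    by learning spot embeddings with a dual-graph neural network. A spatial
    proximity graph and a gene-expression similarity graph are encoded by
    multi-view graph convolutions with attention fusion; training jointly
    optimises a zero-inflated negative binomial reconstruction of raw counts,
    a cross-view consistency constraint, a spatial smoothness regulariser,
    and a Deep Graph Infomax contrastive objective with adaptive hard-negative
    mining. Domains are called by K-means on the learned embeddings. Includes
    a ground-truthed synthetic data generator, readers and writers for h5ad
    and MatrixMarket inputs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    igraph,
    mclust,
    Seurat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
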