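Package: mechanotec
Title: Temporal Expression Clusters and 3D Genome Reorganization Under
    Mechano-Confinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links temporal transcriptional responses to cell
    mechano-confinement with three-dimensional genome structure. Provides
    Ward-D2 clustering of log fold-change trajectories with an adaptive
    dendrogram cut and silhouette gating into temporal expression clusters
    (TECs), an eight-state subcompartment ranker based on the leading
    eigenvector of observed/expected Hi-C correlation with consensus and
    switch classification, Hi-C matrix statistics (iterative-correction
    balancing, exact downsampling, Poisson significant-interaction calling
    with replicate consensus, insulation-score TAD boundaries, a simplified
    negative-binomial differential contact test), a beads-on-string
    Monte-Carlo embedder with radial-position analytics, nonmetric
    multidimensional scaling of interchromosomal contact profiles, and a
    synthetic-data generator that plants all of the statistical structure
    the analyses assume so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
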