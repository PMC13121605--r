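Package: imctme
Title: Spatial Single-Cell Analysis of the Tumor Microenvironment from
    Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for imaging-mass-cytometry (IMC) single-cell spatial
    analysis of tumor and adjacent tissue: per-cell feature extraction from
    multichannel ion-count images and segmentation masks, cell-wise
    non-negative spillover compensation and arcsinh transformation, Boolean
    threshold/polygon gating into immune compartments, kNN-graph Leiden
    clustering with dataset-wide z-scoring, an ImageJ-faithful tumor-mask
    generator (Gaussian blur, Otsu threshold, count-based morphology, exact
    Euclidean distance transform), nearest-cluster distance and fixed-radius
    neighborhood statistics between T-cell populations, patient-level cluster
    frequency testing, and a companion scRNA-seq stage (count normalization,
    marker-predicate gating, binned-control gene-module scoring for
    progenitor- vs terminally-exhausted CD8 T-cell states, Wilcoxon marker
    ranking). A synthetic-data generator produces ground-truth regions of
    interest and expression matrices so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    uwot,
    Matrix,
    tiff,
    yaml,
    pracma,
    withr,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    arrow,
    mclust,
    knitr
Config/testthat/edition: 3
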