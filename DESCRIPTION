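Package: cellularity
Title: Tumor Content Ratio Estimation from H&E Images by Density-Map
    Cell Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the tumor content ratio (TCR) of H&E-stained tissue
    regions by detecting and classifying individual cells with a compact
    fully convolutional density-map regressor. Includes construction of
    gold-standard cell labels from three annotators by distance grouping
    and majority aggregation, stain-space data augmentation for robustness
    to site and scanner variation, bipartite-matching evaluation with an
    extended confusion matrix, cohort-level error statistics including a
    site-dependency index, and a seeded synthetic H&E tile generator so
    the whole pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
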