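Package: wildetect
Title: Detection and Counting of Wildebeest-Sized Animals in Sub-Meter
    Satellite Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for locating and counting very small
    (<= 9 pixel) animals, such as migrating wildebeest, in sub-meter
    multispectral satellite imagery. Point annotations are fused across
    observers and rasterized into 3x3-pixel segmentation masks; a compiled
    U-Net trained with the Tversky loss under a K-fold ensemble produces
    per-pixel presence probabilities; connected components of the
    thresholded ensemble map are split into individual animals by K-means
    with a fixed per-animal pixel footprint; detections are scored against
    reference points by radius-limited one-to-one matching
    (precision/recall/F1 and precision-recall curves with trapezoidal AUC);
    census counts carry t-based confidence intervals and are summarized as
    point-density hotspot rasters and count-per-square-kilometre
    histograms. A seeded synthetic-scene generator emulating satellite
    radiometry, herd aggregation patterns and confuser objects makes every
    stage testable without proprietary imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
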