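Package: thermoseg
Title: Tumor Segmentation from Intraoperative Thermal-Infrared Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-pixel segmentation of brain-tumor tissue from cold-stress
    thermal-infrared video of the exposed cortex. Implements the full
    analysis pipeline: landmark-based affine co-registration of a
    visible-light tumor boundary onto the thermal grid, time-domain feature
    extraction (exponential thermal-recovery fit with goodness-of-fit
    gating, temperature variation, distributional moments, sample entropy),
    frequency-domain features from Morlet wavelet coherence against a
    randomized tumor reference over 60 bands in [0.015, 2] Hz, per-patient
    two-sample feature screening with Bonferroni correction, and
    per-patient RBF-kernel support vector machine classifiers with a
    balanced 20/20/60 split and 10-fold cross-validation. Includes a
    synthetic cold-stress thermal-video simulator so the pipeline is fully
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mgcv,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
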