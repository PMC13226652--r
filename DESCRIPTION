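Package: magcardia
Title: Self-Supervised Contrastive Representation Learning for Multichannel Magnetocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating, preprocessing and learning representations from
    64-channel magnetocardiogram (MCG) recordings. Includes a current-dipole field
    simulator with class-conditional cardiac effects, zero-phase Butterworth/notch
    preprocessing, an SVD-based beat-aligned signal-to-noise quality filter, a
    SimCLR-style augmentation suite and NT-Xent contrastive pretraining of a temporal
    convolutional encoder, task-specific probing heads with patient-stratified
    cross-validation, and Grad-CAM temporal and spatial attribution projected onto
    the sensor array.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    Rcpp,
    rlang,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
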