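Package: renoquant
Title: Automated Kidney Parenchyma Segmentation and GFR Quantification
    for Quantitative SPECT/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for measuring glomerular filtration rate
    (GFR) from quantitative 99mTc-DTPA SPECT/CT: a modified 3D U-net with
    pre-activation residual blocks and a soft-Dice loss segments the renal
    parenchyma on CT, the resulting volumes of interest are applied to the
    co-registered quantitative SPECT to obtain percent injected dose (%ID),
    and %ID is converted to per-kidney GFR and a body-surface-area
    normalized bilateral total. Includes a digital kidney phantom generator
    (paired CT-like and SPECT-like volumes with ground-truth parenchyma
    masks and known %ID), an emulator of sparse-slice manual VOI drawing,
    volumetric NIfTI I/O and preprocessing (resampling, cropping, mask
    smoothing), and an evaluation harness (Dice, MAPE, R-squared,
    Bland-Altman, k-fold cross-validation, kidney-status group reports).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    generics,
    jsonlite,
    optparse,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
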