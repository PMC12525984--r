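Package: canopyspec
Title: Hyperspectral Plant Stress Analysis with Chemometric Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting abiotic stress severity in
    plant canopies from visible/near-infrared (VNIR) hyperspectral image
    cubes. Covers radiometric calibration against white and dark reference
    frames, pseudo-colour HSV segmentation of the plant canopy, region-of-
    interest spectral extraction, scatter-correction preprocessing (standard
    normal variate, multiplicative scatter correction, Savitzky-Golay
    smoothing and derivatives, normalisations), narrowband vegetation indices
    with ANOVA and Duncan multiple-range grouping, successive projections
    algorithm (SPA) wavelength selection, PLS-DA, shrinkage LDA and RBF-SVM
    severity classifiers with stratified splitting and cross-validated
    tuning, and pixel-wise chemical severity maps built from PLS-DA
    regression coefficients. A seeded synthetic scene and spectra generator
    emulates stressed canopy reflectance so the full pipeline is testable
    without access to greenhouse data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    signal,
    e1071,
    pROC,
    jsonlite,
    yaml,
    png,
    tiff,
    rlang
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
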