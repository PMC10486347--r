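Package: carptex
Title: Non-Invasive Muscle Texture Prediction from Skin Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for predicting muscle texture profile analysis
    (TPA) indicators of live fish from visible/near-infrared (400-1000 nm) skin
    hyperspectral images. Covers reflectance calibration against white and dark
    references, Savitzky-Golay spectral smoothing, region-of-interest mean
    spectra, regression-coefficient (RC) wavelength selection, six calibration
    models (PLSR via NIPALS, interval PLS variants iPLS/SiPLS/BiPLS, least-squares
    support vector machine regression, and a backpropagation neural network),
    calibration/prediction metrics (r, RMSEC, RMSEP), best-model ranking, and
    pixel-wise texture prediction maps. Includes a synthetic-data generator that
    emulates the spectral and texture structure of carp skin so the full workflow
    is testable without proprietary data, plus ENVI and portable cube I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
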