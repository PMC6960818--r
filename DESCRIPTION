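Package: hybridcal
Title: Hybrid Drift and Interference Calibration for Ion-Selective Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivariate calibration of an ion-selective electrode
    (ISE) array with an electrical-conductivity probe, as used for monitoring
    NO3, K, Ca and Mg in hydroponic nutrient solutions. Implements two-point
    normalization (TPN) drift compensation based on the simplified Nernst
    equation, a feed-forward neural network trained with the
    Levenberg-Marquardt algorithm, and the hybrid TPN-ANN pipeline that feeds
    drift-corrected electromotive forces into the network. Includes a
    physics-motivated sensor simulator (Nikolsky-Eisenman responses with
    session drift, cross-ion interference and noise), a 3-level fractional
    factorial solution designer, and evaluation metrics (RMSE, CV, ordinary
    least-squares slope with confidence interval) so the whole method can be
    exercised and validated without laboratory hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
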