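Package: parashim
Title: Virtual Parallel-NMR Spectrometer and Deep-Regression Shimming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates a two-channel parallel NMR probehead with
    spherical-harmonic shim coils, cross-channel coupling, and a virtual
    receiver, and implements an AI-driven shimming pipeline on top of it:
    online construction of (spectrum, action) training sequences under
    Gaussian shim distortions, the normalization and augmentation scheme,
    a convolutional-recurrent deep regression model trained with Adam on a
    Huber loss under a sequence-length curriculum, the random-then-predictive
    shimming episode loop, spectral quality metrics (FWHM with a pseudo-Voigt
    fallback for split peaks, direction ratio, success rate), and classical
    baselines (per-shim parabolic interpolation, Nelder-Mead simplex,
    successive parabolic interpolation with empirical convergence-order
    estimation) with exact acquisition accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    minpack.lm,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
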