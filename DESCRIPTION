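Package: cc1decode
Title: Canonical-Correlation Coding Subspaces for Dual-Region Neural Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying low-dimensional sensory coding subspaces
    shared between a cortical neural population and an upstream population via
    canonical correlation analysis (CCA), and for quantifying how close
    decoding from the first canonical component (CC1) comes to the optimal
    linear decoder. Provides an analytic track for dual-population Gaussian
    stimulus-response models (closed-form CCA, Fisher-optimal readouts,
    Gaussian-integral decoding accuracy, Monte-Carlo parameter sweeps) and an
    empirical track for trial-by-neuron spike-count tables (sample CCA,
    best-threshold classifiers, brute-force 2D optimal decoding,
    cross-validation, upstream-resampling experiments), together with a
    dual-region Poisson spike-count simulator with controllable signal and
    shared-noise structure.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
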