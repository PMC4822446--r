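Package: oscouple
Title: Coupling Functions Between Cortical and Cardiorespiratory Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and analysis of cross-frequency phase-phase
    coupling functions between cortical (delta, theta, alpha, gamma),
    respiratory and cardiac oscillations. Provides band-limited phase
    extraction (zero-phase FIR filtering, Hilbert protophases and the
    protophase-to-phase transformation), dynamical Bayesian inference of
    coupled stochastic phase oscillators over sliding windows with prior
    propagation, reconstruction and decomposition of coupling functions
    into direct and indirect components, strength and similarity-of-form
    measures, surrogate significance testing, and rank-based group
    comparison. Includes a stochastic phase-oscillator simulator for
    generating multi-group synthetic cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    purrr
Config/testthat/edition: 3
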