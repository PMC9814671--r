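Package: arnoldweb
Title: Phase-Space Analysis of Unimolecular Dissociation in a Coupled
    Morse-Oscillator Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classical trajectory study of intramolecular vibrational
    energy redistribution and dissociation in a three-degree-of-freedom
    local-mode triatomic model (two Morse stretches and a harmonic bend
    with kinetic momentum coupling). Provides exact Morse/harmonic
    action-angle transforms, adaptive high-order symplectic-quality
    propagation with dissociation event detection and fast Lyapunov
    indicator (FLI) tangent dynamics, microcanonical and fixed-angle-slice
    ensemble generators, survival probability and lifetime distributions
    with constrained multi-exponential fits, analytic resonance lines and
    junction geometry of the Arnold web with Chirikov resonance-overlap
    estimates, and Morlet-wavelet ridge extraction of instantaneous mode
    frequencies with frequency-ratio-space densities and resonance-locking
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
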