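Package: resurgenav
Title: Markov Kinetic Modelling of Resurgent Sodium Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voltage-clamp simulation and rate-constant fitting for a nine-state
    Markov kinetic model of voltage-gated sodium (Nav) channel gating with
    parallel fast and slow inactivation pathways, of the kind used to describe
    the transient (I_NaT), persistent (I_NaP) and resurgent (I_NaR) Nav current
    components of cerebellar Purkinje neurons. Provides matrix-exponential
    propagation of state occupancies through arbitrary step/ramp protocols,
    the standard measurement conventions (peak and persistent current, 1/e decay
    time constants, Boltzmann and single-exponential fits), a library of
    optimization and figure-level protocols returning tidy summary curves, a
    constrained Nelder-Mead fitter for the 24 free rate parameters, and a
    pluggable open-channel-block comparison topology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
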