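Package: phasecrit
Title: Long-Range Temporal Correlations in Phase Synchronization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.net", role = c("aut", "cre"))
Description: Detects long-range temporal correlations (LRTCs) in the
    moment-to-moment fluctuations of phase synchronization between pairs of
    oscillatory time series. Instantaneous phases are extracted with the
    analytic signal, the unwrapped phase difference is differenced to a rate
    of change, and its scaling is quantified by detrended fluctuation
    analysis (DFA). A maximum-likelihood model-selection step (ML-DFA) fits
    the log-log fluctuation plot with a battery of candidate curve families
    and accepts the DFA exponent only when the straight line minimises the
    small-sample-corrected AIC. The package ships the generative models used
    to validate the framework: FARIMA surrogate signal pairs with a known
    phase-difference exponent, a two-dimensional Ising model with sub-lattice
    time series, a noisy mean-field Kuramoto model, and a delayed
    weighted-network Kuramoto model with a synthetic connectome, hemisphere
    disconnection and degree/weight-preserving randomization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
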