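Package: ifmicrostate
Title: Instantaneous-Frequency Microstate Analysis of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments resting-state EEG into instantaneous-frequency (IF)
    microstates: band-limited signals are Hilbert-transformed, the
    unwrapped-phase derivative gives per-channel IF time series, spatially
    z-scored IF topographies are clustered by k-means and refined by a
    first-order hidden Markov model with Gaussian emissions shared across
    participant groups, and per-participant Viterbi state sequences yield
    mean dwell times, fractional occupancies, and empirical transition
    matrices. Includes group-comparison statistics (normality-gated
    Welch/Student t or Mann-Whitney tests with Benjamini-Hochberg FDR,
    signed significance maps, power and effect-size helpers) and a
    Markov-switching oscillation simulator that provides ground-truth state
    sequences for validation.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
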