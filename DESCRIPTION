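Package: tremortrack
Title: Adaptive Phase Tracking and Phase-Locked Stimulation for Wrist-Worn Tremor Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time instantaneous phase estimation of Parkinsonian rest
    tremor from triaxial wrist accelerometry. Implements a bank of recursive
    noise-driven harmonic-oscillator phase trackers (3 axes x 7 center
    frequencies) with self-tuning selection of the dominant axis and center
    frequency, streaming Butterworth offset removal, phase-locked stimulation
    triggering with a per-frequency error budget, the two-stage in-clinic
    random-search protocol, a synthetic tremor generator with ground truth,
    and an offline Hilbert-transform validation and statistics layer
    (wrap-corrected phase error, state-amplitude profiles with
    Bonferroni-corrected resampling limits, rank-sum envelope comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
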