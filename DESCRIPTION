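Package: gaitevents
Title: Automatic Gait Event Detection for Regular and Perturbed Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects touchdown (TD) and liftoff (LO) gait events in regular,
    slip- and trip-perturbed walking from ground reaction force, marker, or
    segment-angle time series. Implements the full pipeline: a synthetic
    perturbed-gait simulator with exactly known events, zero-phase Butterworth
    preprocessing, impulse-to-smooth target encoding via a double-gamma
    (HRF-style) kernel, a bidirectional GRU sequence model trained with a
    custom weighted squared-error loss, constrained peak decoding of the model
    output into event times, and tolerance-based evaluation (50 ms / 30 ms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
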