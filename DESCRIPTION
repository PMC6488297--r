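Package: somnocirc
Title: Sleep Architecture, EEG Spectral Power, and Circadian Wheel-Running
    Analysis for Rodent Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for epoch-scored rodent sleep and circadian phenotyping:
    hypnogram architecture metrics (time in state, bout structure, sleep-onset
    latency), epoch-based EEG power spectral analysis on a fixed 0.781 Hz bin
    grid with state-specific and baseline-window normalization schemes,
    sleep-deprivation homeostasis reports (deprivation efficacy, recovery
    latencies, delta-power rebound, group spectral comparisons with
    Benjamini-Hochberg correction), and wheel-running circadian analysis
    (actograms, Sokolove-Bushell chi-squared periodogram, activity
    onset/offset, alpha, weekly summaries). Includes a synthetic-data module
    that generates hypnograms, EEG spectra/signals, and wheel-count series
    with known ground truth so every analysis stage can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    mgcv,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
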