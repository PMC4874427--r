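Package: flighttones
Title: Harmonic Convergence Analysis of Paired Mosquito Flight Tones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterise harmonic convergence between
    the flight tones of paired mosquitoes recorded on separate audio
    channels. Extracts instantaneous wing-beat frequency from raw audio via
    ridge-tracked time-varying filtering and analytic-signal phase
    demodulation, builds instantaneous frequency-ratio and separation
    series for pairs, detects convergence events with a piecewise aggregate
    approximation and integer-ratio tolerance bands, and quantifies
    interactions with windowed histogram-overlap and local
    coefficient-of-variation metrics. Includes a seeded synthetic
    flight-tone simulator with scripted convergence episodes for validating
    the full pipeline, a randomized non-interacting pairing protocol as a
    null model, and cohort-level summary statistics. All analysis functions
    take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
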