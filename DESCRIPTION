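Package: fovealmask
Title: Foveal-Feedback Masking Analysis for Peripheral Character Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying foveal feedback in peripheral object
    recognition with dense stimulus-onset-asynchrony sampling. Provides
    calibrated bandpass-filtered pink-noise stimulus synthesis, generative
    equal-variance signal-detection observers with transient and periodic
    foveal masking, Hautus-corrected d-prime time courses over time relative
    to peripheral onset (TPO), stratified permutation tests for performance
    dips and between-band masking strength, Hanning-tapered amplitude spectra
    for behavioral oscillations, adaptive-procedure simulators (QUEST,
    2-up-1-down staircases) and maximum-likelihood psychometric fits with
    70.7%-accuracy contrast thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    png,
    withr
Suggests:
    tidyr,
    testthat (>= 3.0.0),
    pracma,
    signal,
    ggplot2
Config/testthat/edition: 3
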