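Package: bciwall
Title: SNR-Wall Detectability Analysis for Single-Channel EEG Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides whether consciously generated EEG changes can be detected
    at all in a single-channel scalp recording contaminated by non-stationary
    noise (facial EMG bursts, eye blinks, saccades, mains interference). The
    recording's SNR-wall is computed from sliding-window noise-variance
    extrema and compared against its signal-to-noise ratio, where the
    conscious signal power is estimated from the P300 evoked potential.
    Includes the underlying energy-detector theory with a Monte-Carlo
    verifier, five causal EEG pre-filtering chains, a seeded synthetic-EEG
    generator with task presets, and group-level detectability testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
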