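Package: thetasweeps
Title: Generative Models and Analysis of Hippocampal Theta-Phase Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates place-cell spiking on linear tracks under three
    generative theta-sweep schemes (spatial, temporal and
    behavior-dependent) and provides the full analysis pipeline used to
    discriminate between them: theta phase extraction from the local
    field potential, place-field detection and size measurement, phase
    precession slope estimation by orthogonal distance regression with
    circular wrapping, per-theta-cycle Bayesian position decoding with
    theta-trajectory length estimation, and a model-comparison harness
    contrasting population-level and within-field running-speed effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    utils,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
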