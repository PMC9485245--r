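Package: spiralflow
Title: Spiral-Space Optic Flow Tuning and Microstimulation Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analysing four-alternative forced-choice
    (4-AFC) roll and heading discrimination experiments with optic flow in the
    3D spiral stimulus space. Provides an idealized dot-cloud stimulus model
    with screen-plane velocity templates, generators and statistics for
    multiunit spiral-space tuning (spiral index, direction d-prime, ROC
    discriminability, clustering index, receptive-field flow-similarity
    index), a labelled-line decision model that injects microstimulation
    effects under three readout variants, and a psychophysics layer:
    psychometric constructions for 4-AFC data, binomial maximum-likelihood
    cumulative-Gaussian fits, probit regression tests for
    microstimulation-induced shifts, signed and threshold-normalized PSE
    shifts, choice-change indices and correct-rate analyses, plus an
    end-to-end simulate/analyze/recover pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
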