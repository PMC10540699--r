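Package: oddbeat
Title: Simulation and Analysis of Rhythmic Auditory Oddball EEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates musical-scale tone sequences that factorially manipulate
    content ("what") and timing ("when") predictions, simulates 64-channel EEG
    with controllable neural entrainment, mismatch responses and artifacts, and
    analyses the result: zero-phase filtering and blink removal, denoising
    source separation, robust trial averaging, inter-trial phase coherence
    (ITPC) at the element and pair presentation rates, channel-by-time
    repeated-measures ANOVA maps with cluster-level permutation inference, a
    planned congruence (deviant-type by timing-condition) contrast, behavioral
    scoring of a repetition-detection decoy task, and brain-behavior index
    correlations with Cook's-distance outlier screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
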