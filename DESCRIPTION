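Package: replaykit
Title: Hippocampal Replay Detection and Sequence Analysis for Two-Track Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal place-cell recordings from
    two-linear-track sessions: naive Bayes position decoding from spike counts,
    sharp-wave-ripple/multi-unit-burst candidate event detection, replay scoring
    by weighted correlation against three circular-shift shuffle nulls, Bayesian
    track-bias assignment, theta-cycle and theta-sequence detection, putative
    sleep scoring from immobility and multi-unit activity (with an LFP-based
    control), place-cell classification and population-vector remapping
    analysis, and replay-rate/bias/regression quantifications linking awake
    activity to subsequent sleep replay. Includes a seeded synthetic two-track
    session generator with ground truth so every stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
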