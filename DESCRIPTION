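Package: iettrack
Title: Consensus-Based Scoring and Item Analysis for Inferential Emotion Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous two-dimensional (valence-arousal)
    affect rating time series collected with the Inferential Emotion Tracking
    paradigm. Implements the Informal Cultural Consensus Model (per-video
    consensus trajectories as first principal-component factor scores,
    Pearson-correlation accuracies, Fisher-Z pooling), reliability diagnostics
    (bootstrap confidence intervals, circular-shift permutation nulls,
    leave-one-out difficulty-function correlations, random-responder
    flagging), a Spearman/partial-Spearman correlation battery with Bonferroni
    correction and permutation tests, and Monte-Carlo video-subset item
    analysis (subset effect curves, best-video selection, chunked
    cross-validated correlations, median/quartile group splits). A synthetic
    cohort generator with known ground truth makes every stage testable
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
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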