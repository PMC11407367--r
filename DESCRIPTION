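Package: bibeta
Title: Ideal-Deviation Multicriteria Scoring with the BI-Beta Index
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the BI-beta multicriteria decision-making method:
    a six-stage pipeline that scores decision alternatives against weighted
    criteria by measuring absolute deviations from per-criterion ideal
    values, re-expressing them so that smaller deviation is better,
    compressing with a natural-logarithm transform, and normalising each
    alternative's weighted total against the best attainable profile to a
    0-100 index. Includes the neutral weighting scheme used by the Global
    Health Security Index (GHSI), an ingester that turns GHSI-style wide
    CSV tables into decision matrices, tie-aware Spearman and Kendall rank
    concordance tests for comparing score-induced rankings, a seeded
    synthetic decision-problem generator with planted best/worst
    alternatives, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
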