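Package: coopmaze
Title: Scoring and Simulation of an Automated Two-Lane Social Cooperation Maze
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Replays time-stamped position tracks of one or two rats in a
    120 cm x 40 cm two-lane maze through the cooperation scoring rules of an
    automated behavioral assay: a zone-based trial state machine that emits
    mutual-reward and coordination-break events, per-session behavioral
    metrics (rewards, locomotor activity, efficacy index, A-to-C latency),
    and learning-curve aggregation across days and pairs. A coupled
    stochastic two-agent simulator with per-individual learning generates
    realistic synthetic sessions covering divider, contextual-cue, sex, and
    solitary experimental arms, so every scoring rule and metric is testable
    without hardware or animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
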