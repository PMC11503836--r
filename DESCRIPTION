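Package: herdtrack
Title: Confidence-Tiered Multi-Object Tracking and Behavior Analytics for Livestock Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracking-by-detection for barn-camera livestock monitoring. Links
    per-frame detector output into animal identities with a two-round,
    confidence-tiered association cascade using distance-IoU and appearance
    costs, a constant-velocity Kalman filter, and a cubic-spline virtual
    observation re-update that repairs trajectories after occlusion gaps.
    Includes MOTChallenge-format readers and writers, the standard tracking
    metric suite (HOTA, MOTA, MOTP, IDF1, MT/ML, identity switches), a seeded
    synthetic barn-scene simulator for desk-scale testing, and behavior
    time-budget analytics over the seven-class cattle ethogram.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
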