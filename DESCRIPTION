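Package: cybervig
Title: Simulation and Trend Analysis of a Three-Screen Cyber Vigilance Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A headless, seedable simulator of a three-screen network-defense
    vigilance task together with its scoring metrics and trend-analysis
    pipeline. Workload is parameterized by signal salience (icon flicker
    frequency, 20-48 Hz), background event rate (8-16 critical signals per
    minute) and cognitive load (1-4 near-critical chart columns held in
    working memory), either fixed at the most difficult values (static mode)
    or ramped linearly over a 60-minute trial (dynamic mode). A discrete-event
    engine generates honeyfile flicker alerts, a self-paced threat-rating
    queue and anomaly-detection frequency charts, classifies every signal into
    exactly one hit, miss or false-alarm outcome, and a parameterized
    synthetic-operator model (learning, fatigue, workload penalties) converts
    stimulus streams into plausible response streams so cohorts of simulated
    participants can be generated without human testing. Scoring aggregates
    outcomes into 2-minute-bucket correct-detection percentage curves per
    screen and pooled; the analysis suite provides the Mann-Kendall trend
    test, Sen's slope with rank-based confidence band, the Durbin-Watson
    autocorrelation diagnostic with embedded Savin-White bounds, split-half
    reliability, and a publication-shaped trend report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
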