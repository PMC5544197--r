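Package: ranksig
Title: Rank-Based Signature Classification for Expression Cohorts
Version: 0.1.0
Authors@R:
    person("MultiOmics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Two-group classification of expression profiles by per-sample
    rank signatures compared with a weighted enrichment-score distance.
    Provides stratified cross-validation, probe-label permutation tests,
    a genetic-algorithm signature optimizer, biomarker extraction as the
    union of per-sample signatures, exact rank-sum differential statistics,
    hypergeometric over-representation analysis with step-down Bonferroni
    correction, HOMA-IR based extreme-group cohort selection, and a
    synthetic cohort generator emulating a two-colour log-ratio microarray
    design for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
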