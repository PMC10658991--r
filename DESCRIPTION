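Package: reosig
Title: Relative Expression Ordering Signatures for Recurrence Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and application of rank-based gene-pair prognostic
    signatures built on within-sample relative expression orderings (REO),
    the top-scoring-pair family of classifiers. Implements the full
    two-cohort discovery funnel: age-stratified differential expression
    screening (Wilcoxon rank-sum), binary REO-indicator screening by
    univariate Cox proportional-hazards regression, cross-cohort
    consistency and gene-redundancy filtering, and forward-stepwise
    selection maximizing Harrell's concordance index under a
    strict-majority voting classifier. Includes survival evaluation
    (Kaplan-Meier, log-rank, uni/multivariate Cox, Fisher's exact
    association tests) and a synthetic two-cohort survival simulator with
    planted gene pairs and known ground truth for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
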