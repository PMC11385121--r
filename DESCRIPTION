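Package: trialhte
Title: Win-Ratio, Bayesian Reanalysis and Treatment-Effect Heterogeneity for Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reanalysis toolkit for two-arm randomized trials in critical care,
    built around the dopamine-versus-norepinephrine shock trial (SOAP II).
    Provides stratified generalized pairwise comparisons (win ratio) over
    ordered endpoint hierarchies with bootstrap and asymptotic inference;
    Bayesian logistic and linear outcome models under a neutral treatment
    prior with probability-of-direction, highest-density-interval and
    region-of-practical-equivalence summaries; bridge-sampling Bayes factors
    gating interaction reporting; risk-based heterogeneity of treatment
    effect over recalibrated severity-score quartiles; effect-based
    heterogeneity via an S-learner with a counterfactual recommendation
    rule; and a synthetic cohort generator calibrated to the trial's
    published marginal distributions so the full pipeline is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
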