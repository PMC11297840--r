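Package: prtrees
Title: Pseudo-Value Regression Trees for Survival Probability Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-parametric estimation of individual-specific survival
    probabilities from right-censored data via pseudo-value regression
    trees: jackknife pseudo-observations of the Kaplan-Meier estimator
    are computed on a small grid of time points, a multivariate
    conditional-inference tree with permutation-test split selection is
    grown on the pseudo-value vectors, and cascaded component-wise
    gradient-boosting models with a complementary log-log squared-error
    loss, linear covariate base-learners and a monotone time
    base-learner are fitted in the nodes, linked by time-dependent
    offsets.  Includes the standard GEE pseudo-value regression
    baseline, censoring-weighted evaluation metrics (Brier score,
    truncated concordance index), and generators for two lognormal
    simulation designs with exact ground-truth survival functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
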