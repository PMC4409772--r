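Package: copdce
Title: Comparative Effectiveness Pipelines for Claims-Based COPD Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for new-user, active-comparator comparative effectiveness
    studies of inhaled corticosteroid/long-acting beta-agonist combinations
    (budesonide/formoterol vs fluticasone/salmeterol) in administrative
    claims data. Provides a synthetic claims-database generator with known
    ground truth, waterfall-style cohort construction with per-criterion
    attrition, claims-based adjudication of COPD exacerbation and pneumonia
    events (14-day merging and attribution rules), random-forest propensity
    score estimation with 1:1 greedy matching and balance diagnostics,
    covariate-adjusted negative binomial, Cox, logistic, ordinal and linear
    outcome models, and a negative binomial sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    MASS,
    randomForest,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
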