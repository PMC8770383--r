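Package: anemiaMSM
Title: Marginal Structural Cox Models for Time-Varying Anemia in Early
    Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal analysis of time-varying anemia status on renal,
    cardiovascular and mortality outcomes in subjects at the onset of
    impaired renal function (first eGFR below 60 mL/min/1.73 m2).
    Builds analysis cohorts from longitudinal health-checkup, claims and
    enrollment tables; derives composite renal and cardiovascular
    endpoints; estimates stabilized inverse-probability-of-treatment
    weights from pooled logistic (or multinomial) models with a restricted
    cubic spline time intercept; fits marginal structural Cox models with
    cluster-robust sandwich variance; produces counterfactual survival
    curves from the weighted Breslow estimator; and runs the associated
    sensitivity battery (weight truncation, Fine-Gray competing risks,
    hemoglobin-quintile exposure, propensity-score matching, eGFR slopes).
    A synthetic longitudinal cohort generator with known causal structure
    and genuine time-dependent confounding makes every stage testable
    without access to proprietary claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cmprsk,
    optparse
Config/testthat/edition: 3
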