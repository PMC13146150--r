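Package: edcadence
Title: Retraining-Cadence Simulation for Emergency-Department Admission
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how often a clinical admission-prediction model
    should be retrained. Generates seeded synthetic paediatric
    emergency-department presentation streams with seasonal overdispersed
    volumes, class imbalance and injectable covariate/concept drift; fits a
    stacking ensemble (gradient-boosted trees plus optional neural-network and
    penalised-linear base learners under a logistic meta-learner, with
    minority oversampling) through a rolling prospective simulation at ten
    retraining cadences on a pseudo-week grid; and evaluates discrimination
    (AUROC), probability calibration (Brier, slope/intercept, expected
    calibration error) and aggregate bed-demand calibration (absolute mean
    daily bed error, AMDBE), with drift diagnostics (domain classification,
    PCA reconstruction error, repeated-period monitoring) and a paired
    Wilcoxon cadence comparison with Bonferroni correction and rank-biserial
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    xgboost,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    glmnet,
    nnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
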