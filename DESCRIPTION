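Package: contextrisk
Title: Context-Specific Perinatal Risk Estimation with Discrete Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for explainable risk stratification in categorical clinical
    cohorts, built around discrete Bayesian networks. Implements BIC-based
    hill-climbing structure learning with clinical edge blacklists, maximum
    likelihood and Dirichlet-smoothed parameter estimation with an explicit
    "unknown" state for missing data, exact inference by variable elimination,
    scenario-based absolute and relative risk queries with bootstrap percentile
    confidence intervals, effect-modification (interaction) scanning, categorical
    feature selection (chi-square, mutual information, Jaccard redundancy
    pruning, subset search over logistic models), stratified evaluation
    (cross-validation, AUC, rare-scenario subsets), and a synthetic obstetric
    cohort generator with a planted fetal-sex by preexisting-diabetes effect
    reversal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet
Config/testthat/edition: 3
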