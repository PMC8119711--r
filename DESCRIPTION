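Package: palcohort
Title: Calibrated Cohort Simulation and Robustness Analyses for
    Sex-Modified Effects on Paired-Associate Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how biological sex modifies the association
    between smoking (and a cardiovascular-disease composite) and
    paired-associate verbal memory in large web-recruited cohorts.
    Provides a cohort data model with validation and descriptive
    between-group chi-square tables; a synthetic cohort generator whose
    defaults reproduce the composition of an 80,000-participant web
    cohort and whose outcome noise can be calibrated so coefficient
    standard errors match published values; covariate-adjusted linear
    models with sex-by-exposure interactions, stratified simple effects
    and lasso stability selection; 1:1 propensity-score matching with
    simulation-based credible intervals; and three resampling engines:
    balanced down-sampling power curves, smoking-status misclassification
    Monte Carlo, and permutation tests for regression coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
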