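Package: snplasso
Title: Candidate-Gene SNP Association and LASSO Stability Selection for
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("snplasso", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of candidate-gene case-control SNP panels:
    per-SNP covariate-adjusted logistic regression under four modes of
    inheritance with likelihood-ratio testing, polytomous (multinomial)
    subphenotype heterogeneity tests, SNP-SNP and SNP-smoking interaction
    scans, min-p permutation correction for multiple testing, and an
    L1-penalized logistic regression engine with unpenalized covariates,
    cross-validated AIC penalty tuning, bootstrap stability selection and
    permutation-corrected post-selection inference. Includes a synthetic
    cohort generator emulating a hospital-based bladder-cancer case-control
    design (tagSNP panel under Hardy-Weinberg equilibrium, categorical
    covariates, stage/grade subphenotypes, p53 immunohistochemistry
    histoscores) so the whole pipeline is testable without access to
    individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
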