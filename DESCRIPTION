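Package: pvep
Title: Pharmacovigilance Signal Detection for Drug-Induced Eosinophilic
    Pneumonia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for spontaneous-report pharmacovigilance analysis of
    drug-induced eosinophilic pneumonia. Parses FAERS-dialect quarterly
    ASCII tables into a normalized report store with FDA-style
    deduplication, extracts cases via a Standardized MedDRA Query term
    set, computes the four-metric disproportionality panel (reporting
    odds ratio, proportional reporting ratio with chi-square,
    information component, empirical Bayes geometric mean) with signal
    positivity rules and multiplicity adjustment, fits Weibull
    time-to-onset models with early/random/wear-out failure typing and
    Kaplan-Meier / Kruskal-Wallis subgroup comparisons, and screens
    risk factors through a univariate filter, LASSO selection with
    10-fold cross-validation, and multivariable logistic regression.
    A synthetic spontaneous-report generator with planted ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    survival,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
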