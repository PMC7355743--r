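Package: pedigrs
Title: Polygenic Risk Score Analysis of Childhood Obesity Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a weighted body-mass-index polygenic risk score (pGRS) from
    quality-controlled genotypes and evaluates it across the three study designs
    typical of paediatric obesity genetics: cross-sectional association and
    prediction (linear/logistic models, quantile contrasts, ROC/AUC with DeLong
    intervals), a gene-by-environment interaction scan with Benjamini-Hochberg
    false discovery rate control, pubertal obesity and insulin-resistance
    trajectory classification with tertile odds ratios, and score-by-treatment
    interaction tests for a weight-reduction trial. A synthetic-cohort
    generator with known ground truth (Hardy-Weinberg genotypes, engineered QC
    failures, additive polygenic phenotypes with a target heritability,
    environment factors with configurable interaction coefficients,
    five-group pubertal trajectories and a two-arm trial) makes every stage
    testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
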