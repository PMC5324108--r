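Package: crcrisk
Title: Environmental and Genetic Risk Stratification for Colorectal Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a colorectal cancer risk-stratification
    model that combines an environmental risk score (count of six modifiable
    binary risk factors), family history, and an additive genetic risk score
    over a 21-SNP susceptibility panel. Provides a synthetic frequency-matched
    case-control cohort generator under Hardy-Weinberg equilibrium, covariate
    derivation and deterministic imputation, propensity-score adjustment for
    the matched design, propensity-quintile case-weighted AUROC with 5-fold
    cross-validation and bootstrap confidence intervals, and projection of
    relative risk scores onto registry cumulative incidence to obtain
    risk-advancement ages, screening sensitivity/specificity/likelihood
    ratios, and Bayes-theorem predictive values.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
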