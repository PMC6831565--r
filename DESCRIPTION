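Package: frailmet
Title: Frailty Index Metabotyping from Untargeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline linking deficit-accumulation frailty
    scoring to untargeted mass-spectrometry metabolomics. Provides frailty-index
    construction and stratification, QC-based robust-spline drift correction and
    RSD filtering of LC-MS feature tables, seeded chained-equations imputation of
    clinical biomarkers, PC-DFA ordination and RUSBoost-CART classification with
    permutation nulls, nonparametric univariate panels with FDR control,
    m/z-based pathway activity-network enrichment, multivariate ROC prediction
    via Monte-Carlo cross-validation with PLS-DA feature ranking, and two-sample
    inverse-variance-weighted Mendelian randomization. A synthetic-cohort
    generator emulating the statistical structure of population frailty studies
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
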