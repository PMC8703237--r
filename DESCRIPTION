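Package: metaboSurrogates
Title: Metabolomics-Based Surrogates for Clinical Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains, evaluates and applies penalized logistic-regression
    surrogates that impute common clinical risk factors from a 1H-NMR
    metabolomics marker panel. Covers the full multi-biobank workflow:
    panel quality control (sample filters, NIPALS imputation, z-scaling),
    derivation of dichotomous clinical variables (including Friedewald LDL
    and CKD-EPI eGFR composites), elastic-net surrogate training with
    double 5-fold cross-validation and leave-one-biobank-out validation,
    metabolome-wide association studies with an effective-number-of-tests
    Bonferroni correction, and clustered Cox survival association with
    stepwise AIC model selection. Ships a synthetic multi-cohort generator
    with planted ground truth so every stage is testable without
    access-restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    glmnet,
    survival,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
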