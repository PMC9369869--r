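Package: metscreen
Title: Screening Indexes for Metabolic Syndrome in Pediatric Severe Obesity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate simple anthropometric and biochemical indexes
    (BMI, BMI-SDS, tri-ponderal mass index, waist-to-height ratio, TG/HDL
    cholesterol ratio, cardiometabolic index, visceral adiposity index) as
    screening predictors of IDF-defined metabolic syndrome in children and
    adolescents with severe obesity. Includes a Gaussian-copula synthetic
    cohort generator with matching synthetic growth references, rule-based
    IDF metabolic-syndrome classification, age standardization of index
    values by polynomial quantile regression, from-scratch ROC analysis with
    DeLong AUC comparison and Youden cutoffs, cutoff-level diagnostic
    metrics with several confidence-interval conventions, age-by-sex cutoff
    trend estimation, and the descriptive and association statistics of a
    screening study (rank tests, Spearman correlation, outlier screening,
    age-adjusted logistic odds ratios), orchestrated by a reproducible
    pipeline with file outputs and a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
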