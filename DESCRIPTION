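Package: transprs
Title: Trans-Ancestry Polygenic Risk Score Evaluation and Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for evaluating polygenic risk scores (PRS)
    across ancestrally diverse populations: PRS computation from weight tables
    and genotype dosages with allele harmonization, reference-panel principal
    component analysis with projection and probabilistic population assignment,
    a post hoc ancestry adjustment that standardizes raw scores by PC-predicted
    mean and variance so a single risk cutoff applies across ancestries, a full
    predictive-performance metrics suite (liability-scale R-squared, AUC
    variants, odds ratio per standard deviation, tail discrimination with
    prevalence-adjusted predictive values, decile calibration), inverse-variance
    weighted meta-analysis, and cross-population effect-size concordance.
    Includes a synthetic multi-ancestry cohort generator (Balding-Nichols
    allele-frequency divergence plus a liability-threshold disease model) so
    every stage can be exercised without restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    pROC,
    optparse
Config/testthat/edition: 3
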