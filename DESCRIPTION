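Package: pathotrial
Title: Biopsy-Stratified Randomised Trial Simulation and Analysis for
    Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machinery for biopsy-driven, pathotype-stratified randomised
    trials in rheumatoid arthritis: a synthetic trial generator with known
    ground truth (negative-binomial synovial expression with a B-cell gene
    module, ordinal immunohistochemistry scores, week-16 clinical visits,
    missingness and dropout); composite disease-activity indices (CDAI,
    DAS28-ESR/CRP, EULAR response) and binary endpoint definitions;
    semi-quantitative histology classification into B-cell poor, B-cell
    rich, germinal-centre-positive and unknown pathotypes; a gene-module
    expression classifier with median cutoff and a cutoff sensitivity
    scan; stratified permuted-block randomization; the trial statistical
    battery (risk differences with Wald intervals, chi-squared and Fisher
    tests, ANCOVA and rank ANCOVA, paired Wilcoxon with an exact tied
    null, nested-logistic interaction likelihood-ratio tests, multiple
    imputation by chained equations with Rubin pooling); and
    two-proportion design and power calculations with a recruitment
    attrition chain.
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
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
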