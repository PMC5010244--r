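Package: stratmet
Title: Genotype-Stratified Integration of Serum NMR Metabolomics and
    Cardiometabolic Risk Factor Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links clustering of cardiometabolic risk factors to SNP
    genotypes and serum 1H-NMR metabolomic profiles. Provides ATP-III
    risk-factor scoring and grouping, SNP quality control (call rate,
    Hardy-Weinberg) and additive logistic association with Bonferroni
    control, 1H-NMR spectral referencing, 0.01-ppm bucketing, total-area
    normalization and metabolite window quantification, PLS-DA
    chemometrics with Venetian-blind cross-validation, permutation
    validation, VIP scores and cross-validated ROC, and a
    genotype-stratified normalized metabolic-difference statistic with
    null-profile flagging. A synthetic-cohort generator emulates the
    statistical structure of population metabolomics studies so the full
    pipeline is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
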