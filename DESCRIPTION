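Package: epiScreen
Title: ER-Stratified Gene Association Screening and Promoter
    Methylation Silencing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis toolkit for estrogen-receptor (ER)
    stratified breast-cancer cohorts: an unsorted singular-value
    (one-sided Jacobi) association screen of a target gene against a
    candidate gene panel with median-quantile selection and cross-stratum
    Venn partitioning; promoter-probe methylation/expression (beta value)
    correlation panels; median-dichotomized Kaplan-Meier overall-survival
    analysis with log-rank tests per stratum; droplet digital PCR Poisson
    quantification and MS-MLPA methylation dosage-ratio calling; and a
    seeded synthetic-cohort generator with planted correlations, expression
    shifts and hazards so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
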