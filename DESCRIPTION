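Package: mbcenrich
Title: Multi-Cohort Mutation Enrichment and Organotropism Analysis for
    Metastatic Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonizes somatic mutation, copy-number and clinical tables
    from heterogeneous targeted-sequencing cohorts and compares alteration
    frequencies between metastatic and primary breast cancer across
    metastatic-site sets. Implements stratified odds-ratio meta-analysis
    with heterogeneity-driven switching between fixed-effects
    (inverse-variance) and random-effects (REML) pooling, cohort-adjusted
    logistic regression, a dual-criterion organotropism caller, a
    pattern-based candidate-driver-mutation scorer for oncogene hotspot and
    tumor-suppressor truncating mutations, and a multi-cohort synthetic
    data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
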