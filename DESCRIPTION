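Package: oncofusion
Title: Multimodal Data Fusion, Evolutionary Dataset Splitting and
    Attention-Based Multiple Instance Learning for Oncology Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multimodal machine-learning analyses of
    patient-centered oncology cohorts. Provides a JSON data model for
    clinical, pathological, blood, ICD-code and tissue-microarray
    immune-density data; per-modality encoding into multimodal patient
    vectors (early fusion); a genetic algorithm that selects
    class-balanced in-distribution and out-of-distribution train/test
    splits by maximising cosine-distance objectives; SMOTE rebalancing
    and Random Forest outcome prediction evaluated over distinct split
    regimes; gated-attention multiple instance learning over
    multi-source instance-embedding bags with per-modality attention
    attribution; Kaplan-Meier survival estimation and
    Wilcoxon-Mann-Whitney comparisons. A seeded synthetic-cohort
    generator emulates the statistical structure of a head-and-neck
    cancer cohort so the full pipeline is testable without restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ranger,
    survival,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
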