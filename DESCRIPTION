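Package: venusscore
Title: Venus Score for Biomedical Dataset Quality and Trustworthiness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring toolkit for the Venus score, a ten-question instrument
    that rates the quality and trustworthiness of biomedical datasets on a
    0-10 scale. Provides the built-in questionnaire with weighted sub-items,
    annotation validation and scoring, multi-annotator merging and Pearson
    inter-annotator agreement, cohort summary statistics, an additive-weight
    replica of the Kaggle Dataset Usability Score with a least-squares
    weight-deduction solver, a crosswalk from Venus questions to EU AI Act
    data-governance requirements, Datasheets for Datasets items and Kaggle
    fields with coverage statistics, datasheet-style report rendering, and
    bundled fixtures for a twelve-dataset biomedical cohort.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
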