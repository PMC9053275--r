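Package: radlabel
Title: Weakly Supervised Labeling of Chest X-Ray Reports and Multi-Label
    Diagnostic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts binary abnormal-sign labels from free-text chest
    radiograph reports using a rule-constrained knowledge graph of
    radiological concepts: sentence segmentation, lexicon-based entity
    recognition, negation and uncertainty classification, and relation
    extraction feed a 25-label sign ontology organized into four anatomical
    regions. Companion tooling covers cohort assembly (deduplication,
    exclusions, label matrices), a cross-validation harness with
    class-weighted binary cross-entropy and mean-probability ensembling,
    multi-label diagnostic evaluation (Mann-Whitney AUC, F1-maximizing
    thresholds, subsample and bootstrap confidence intervals, DeLong tests,
    per-subject concordance), a 4-bit anatomical color-index encoding for
    embedding plots, and synthetic report and score generators for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
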