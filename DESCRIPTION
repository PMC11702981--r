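Package: p53ces
Title: Predicting Non-Mutational p53 Functional Deficiency from Tumor
    Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect reduced p53 tumor-suppressor activity in tumors
    that carry wild-type TP53. Cohort-specific sets of p53-regulated genes
    are selected by differential expression between adjacent normal tissue
    and TP53-truncated tumors, summarized per sample into seven composite
    expression scores (GSVA, ssGSEA, combined Z-score for each gene set, and
    a principal-component score), and used to train a linear
    support-vector-machine classifier that labels wild-type and missense
    tumors as predicted-normal or predicted-reduced-function. The package
    also scores therapy-sensitivity signatures, re-genotypes reported
    variant sites from RNA-seq allele counts, classifies xenograft
    radiotherapy response from survival ratios, and ships a synthetic-cohort
    generator so the full workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
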