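Package: methylTF
Title: Predicting Transcription Factors and Their DNA Methylation
    Binding Preference from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-step sequence-based pipeline for regulatory genomics:
    a screening stage that separates transcription factors (TFs) from
    non-TFs using tokenized sequences and a CLS-embedding classification
    head, and a second stage that predicts whether a TF preferentially
    binds methylated DNA (a "methylation reader", TFPM) using a reduced
    amino-acid alphabet, K-mer composition features, and a radial-kernel
    support vector machine. Includes confusion-matrix and ROC/AUC
    evaluation, stratified cross-validation, hyperparameter grid search,
    proteome-wide ranking by calibrated TFPM probability, and a seeded
    synthetic-data generator with planted composition signals so every
    stage can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
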