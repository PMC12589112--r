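Package: epispec
Title: Epitope-Specific T-Cell Detection from TCR Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to identify and quantify epitope-specific T cells from
    T-cell receptor (TCR) sequencing data. Selects epitope-specific training
    repertoires by local CDR3 motif enrichment against a reference repertoire
    combined with global Hamming-distance similarity, trains Gaussian-process
    classifiers of TCR epitope specificity from CDR3-beta sequences and
    V-beta genes with decision thresholds calibrated to a target false
    positive rate, and quantifies predicted epitope-specific T cells in bulk
    TCR-beta and single-cell TCR-alpha/beta cohorts: read-weighted
    frequencies, Simpson clonality, inter-cohort rank tests, repertoire
    sharing, position-frequency matrices, and phenotype-cluster enrichment.
    Ships a seeded synthetic-repertoire generator used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
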