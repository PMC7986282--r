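Package: CRISPRiScreen
Title: Design and Analysis of Barcoded CRISPRi Pooled Growth Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for genome-wide CRISPR interference (CRISPRi) screening
    in budding yeast and similar compact genomes. Designs up to ten guide RNAs
    per gene using transcription start site windows, zone coverage rules and
    chromatin accessibility; processes barcoded sequencing reads into barcode
    count tables and barcode-to-guide assignments; infers per-barcode selection
    coefficients from pooled competitive growth with a negative-binomial GLM
    and aggregates them to guide-level fitness scores; and fits a calibrated
    logistic model of guide activity from target position, nucleosome occupancy
    and guide sequence. A synthetic-data generator emulates genomes with
    divergent promoters, accessibility tracks, barcoded read libraries with
    synthesis errors and chimeras, and exponential lineage dynamics, so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    pROC,
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
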