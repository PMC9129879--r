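Package: epimem
Title: Quantitative Analysis of Epigenetic Transcriptional Memory Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative assays used to study epigenetic
    transcriptional memory in budding yeast: allele-ratio quantification
    from four-channel Sanger-style chromatograms with standard-curve
    calibration, pooled two-strain competitive fitness as t0-normalized
    log2 odds ratios, a replication-dilution model of histone-mark
    (H3K4me2) persistence with reader-writer maintenance and active
    removal fitted to ChIP time courses, a spherical-shell baseline for
    nuclear-periphery gene localization with replicate-level enrichment
    tests, and delta-Ct arithmetic for qPCR readouts. Includes seeded
    synthetic-data generators emulating each assay so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
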