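Package: erenorm
Title: Expressed Repetitive Elements as Reference Targets for RT-qPCR Normalization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying and validating expressed-repetitive-element
    (ERE) reference targets for RT-qPCR normalization: mismatch-tolerant
    in-silico PCR screening of candidate repeat assays, standard-curve
    amplification-efficiency quality control, geNorm expression-stability
    analysis (M-values, pairwise variation V, optimal reference-target
    count), genomic-DNA carryover assessment from paired +RT/-RT reactions,
    and cross-experiment consensus ranking by exhaustive search or
    cross-entropy Monte Carlo. Includes seeded generators of synthetic Cq
    tables, dilution series, -RT control pairs and transcriptomes with
    embedded repeat cassettes, so the whole workflow is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
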