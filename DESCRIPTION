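Package: fusiontriage
Title: Curation, Prioritization and RT-qPCR Confirmation of Fusion Transcript Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-calling curation of gene fusion candidates from FFPE sarcoma
    RNA sequencing. Reads FusionCatcher-style candidate tables, scores calls as
    fusion-supporting reads per million uniquely mapped reads, annotates
    breakpoints against a GTF gene model (exon-border, intron, frame status),
    applies an auditable artifact filter and prioritization cascade, screens a
    cohort for recurrent secondary fusions, and validates RT-qPCR assays
    (dilution-series amplification efficiency, Cq/Tm gated confirmation
    calls). A synthetic-cohort generator with planted truth makes every stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
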