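Package: vnartools
Title: Annotation, Classification and Screening Analysis of Shark vNAR Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing cloned repertoires of the shark
    immunoglobulin new antigen receptor variable domain (vNAR). Provides
    open-reading-frame and cloning-flank quality control of nucleotide
    inserts, canonical-cysteine anchored delimitation of framework and
    hypervariable regions (CDR1, HV2, HV4, CDR3), rule-based classification
    into vNAR types I, IIa, IIb, III and IV from noncanonical cysteine and
    tryptophan patterns, repertoire diversity summaries (unique sequences,
    unique CDR3s, CDR3 length and cysteine distributions), phage-display
    biopanning and ELISA enrichment analysis, and a seeded synthetic
    repertoire generator with ground-truth labels for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
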