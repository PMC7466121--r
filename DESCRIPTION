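Package: rtsig
Title: Reverse Transcription Signature Profiling of RNA Modifications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reverse-transcription (RT) signature analysis of RNA
    modifications in (t)RNA sequencing data. Builds single-base resolution
    profile tables from read alignments (coverage, orientation-split base
    counts, mismatch rate, arrest rate and three classes of deletion-derived
    jump rates), annotates known modified sites, and compares reaction
    conditions (for example magnesium- versus manganese-buffered reverse
    transcription) with matched-position statistics. A stochastic reverse
    transcription simulator with modification-dependent arrest,
    misincorporation and nucleotide-skipping events provides ground-truth
    synthetic libraries for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
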