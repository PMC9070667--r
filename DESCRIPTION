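Package: clipmotif
Title: Motif Specificity and Target Analysis for an RNA-Binding Protein from
    RNAcompete and iCLIP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the sequence specificity and cellular
    targets of a single-stranded-RNA-binding protein. Implements split-half
    7-mer Z-score scoring of RNAcompete-style probe intensities with
    consensus-motif construction from the top-scored 7-mers; a degenerate
    U-rich motif grammar scanned in windows around iCLIP crosslink positions,
    with cluster extension, bait-overlap statistics, a 50-nt positional
    equivalence rule and contaminant filters; exact and approximate null
    models for motif occurrence in random RNA fragments with Monte-Carlo
    verification and enrichment ratios; Hill-equation binding-curve fitting
    for titration series; and seed-reproducible synthetic-data generators so
    the whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
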