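Package: intronDR
Title: Direct Repeats at Intron-Exon Borders
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects and classifies direct repeats in the sequence windows
    flanking the 5' and 3' intron/exon borders of annotated genes. Implements
    a constrained gapped repeat search (minimum length, minimum percent
    similarity, short mismatch/gap linkers joining identical blocks), an
    exhaustive enumeration oracle for validation, positional classification of
    repeat pairs relative to the splice borders, analytic and Monte-Carlo null
    models for chance repeat matches in fixed-width windows, grouped summary
    statistics, and a synthetic exon-intron-exon generator that plants repeat
    pairs of known geometry and degradation for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    jsonlite,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
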