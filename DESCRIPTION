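Package: ervpbs
Title: Primer Binding Site Variation in Endogenous Retroviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs full-length LTR retroelements from fragmented
    repeat annotations, extracts and scores their tRNA primer binding
    sites (PBS) against primer-tRNA 3' ends, tabulates PBS variant
    frequencies with perfect/common labels, characterises the PBS
    mutation spectrum, scores susceptibility to 3'-derived tRNA
    fragments (tRF3a/tRF3b), dates elements by LTR-LTR percent
    identity, and builds bootstrapped neighbor-joining trees of element
    families. Ships a synthetic-genome simulator with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
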