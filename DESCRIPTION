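Package: mitorearr
Title: Comparative Analysis of Organellar Genome Rearrangements, Repeats
    and RNA Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of small circular organellar
    genomes (plant mitogenomes and plastomes): detection of large direct and
    inverted repeat pairs by gapless seed-and-extend, decomposition of a
    genome pair into locally collinear blocks (LCBs) via unique-anchor
    chaining, encoding of block order as a signed permutation, breadth-first
    search for minimal inversion scenarios including repeat-mediated
    recombination scenarios constrained by repeat copies at block junctions,
    and a simplified comparative predictor of C-to-U and U-to-C RNA editing
    sites in organellar coding sequences with summary statistics. A synthetic
    genome simulator with planted repeats and recorded inversion ground truth
    supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    igraph,
    withr
Config/testthat/edition: 3
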