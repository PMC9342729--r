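Package: plastocomp
Title: Comparative Plastome Analysis: Quadripartite Structure, Repeats,
    Inversions and Hypervariable Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated chloroplast
    (plastid) genomes. Reads GenBank flat files, detects the quadripartite
    LSC/IRb/SSC/IRa partition from sequence alone and reports junction
    genes, scans microsatellites (MISA-style), tandem repeats and maximal
    dispersed forward/palindromic repeats under a Hamming budget, calls
    large inversions from unique-anchor synteny chaining and associates
    them with flanking palindromic repeats, ranks intergenic spacers by
    Kimura two-parameter divergence, and evaluates diagnostic SNP/indel
    marker sites. Includes a synthetic annotated-plastome generator with
    machine-readable ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
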