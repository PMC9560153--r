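Package: orfevo
Title: Discovery and Evolutionary Characterization of Unannotated Translated ORFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proteogenomic pipeline for cataloguing potential open reading
    frames (ORFs) from genome and transcript sequences, screening
    peptide-spectrum matches with a two-round target-decoy false discovery
    rate strategy, scoring synteny-anchored protein similarity across species
    with a zero-gap-penalty Smith-Waterman alignment, inferring
    phylostratigraphic gene ages, de novo origination and losses on a species
    tree, discovering latent classes of loci by finite-mixture EM, and
    summarizing expression and ribosome-profiling support. Includes
    synthetic-data generators with planted ground truth so every stage can be
    exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    ape,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
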