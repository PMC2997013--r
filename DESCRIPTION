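Package: mitescan
Title: Structure-Based Discovery and Evolutionary Analysis of Miniature
    Inverted-Repeat Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for annotating miniature inverted-repeat transposable
    elements (MITEs) in assembled genomes. Detects candidate elements from
    their structural signature (terminal inverted repeats flanked by a target
    site duplication), clusters candidates into families by pairwise identity,
    removes pseudo-element families (N-containing, simple-repeat, or
    nested-in-repeat artifacts), performs a genome-wide homology census with
    intact/fragmentary calling and superfamily classification, and summarises
    family evolution through consensus building, Kimura two-parameter
    insertion ages, sliding-window nucleotide diversity, and median-joining
    haplotype networks. Genomic-context statistics cover chromosome
    distribution tests, gene-proximity classification against a randomised
    insertion null, density correlations, and a germline-silencing
    probability. A synthetic-genome simulator with planted, truth-labelled
    elements supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    ape,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
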