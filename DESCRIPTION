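Package: dictycore
Title: Conserved Core of Developmentally Up-Regulated Genes in Social Amoebae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative developmental transcriptomics toolkit for defining a
    conserved core set of developmentally up-regulated genes across four
    dictyostelid species (Dictyostelium discoideum, D. lacteum,
    Polysphondylium pallidum, D. fasciculatum). Builds ortholog families from
    protein similarity graphs by Markov clustering, calls developmental
    up-regulation with three independent methods (an rpkm threshold caller,
    a negative-binomial test using the four species as evolutionary
    replicates, and a two-strain replicate test), assembles the Venn core
    set, performs hypergeometric GO enrichment with annotation propagation,
    computes mutant-catalogue overlap statistics, and tests whether
    late-peaking developmental genes are more conserved at the protein level.
    Includes a seeded synthetic-data generator with planted ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    withr
Config/testthat/edition: 3
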