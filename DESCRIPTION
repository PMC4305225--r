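Package: binscape
Title: Reference-Independent Visualization and Human-Augmented Binning of
    Metagenomic Fragments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Visualizes assembled metagenomic fragments (contigs or long
    reads) without reference genomes by embedding centered log-ratio
    transformed oligonucleotide signatures into two dimensions with a
    from-scratch Barnes-Hut implementation of t-distributed stochastic
    neighbor embedding. Clusters apparent in the embedding are delineated
    by user-supplied polygons and exported as FASTA bins, and bin quality
    is scored against a universe of 107 bacterial single-copy essential
    genes (completeness and multi-copy contamination). Includes a Markov
    chain mock-community simulator so the whole pipeline is testable
    without external datasets, and a command-line front-end for headless
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Matrix,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
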