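Package: syntegraph
Title: Micro-Synteny Networks and Phylogenetics for Gene Family Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for tracing the origin and diversification
    of a two-domain gene family (the MAM/IPMS type) across related genomes.
    Provides exact Smith-Waterman all-vs-all protein search, collinear-block
    detection by anchor chaining, micro-synteny network assembly with
    k-clique-percolation community detection, PSSM-based protein domain
    scanning with empirical e-values, distance-based gene-tree inference with
    bootstrap, a segment-wise gene-fusion test, duplication-type
    classification, and locus dosage profiling.  A forward genome-evolution
    simulator (speciation, polyploidy, tandem and transposed duplication,
    gene loss, domain loss, gene fusion) supplies ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
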