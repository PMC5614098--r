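Package: miniclust
Title: Cascaded Protein Sequence Clustering, Consensus Alignments and
    Annotation Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for building clustered protein sequence
    databases in the style of Uniclust: redundancy filtering by reduced-alphabet
    hashing, fragment absorption, greedy incremental clustering, greedy
    set-cover clustering with a member reassignment pass, and incremental
    database updates with stable cluster identifiers.  Per-cluster
    center-star multiple sequence alignments (A3M), consensus sequences with
    annotation summary headers, position-specific scoring matrices, iterative
    profile searches for MSA diversification with score-per-residue filters,
    subalignment E-value annotation transfer, and cluster quality evaluation
    via compactness and Gene Ontology, keyword and protein-name consistency
    scores.  Includes seeded synthetic-data generators (homologous families,
    toy ontologies, annotation corpora, domain matches) so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
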