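Package: npsphylome
Title: Phylogenomic Analysis of Fungal Nonribosomal Peptide Synthetase Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenomic analysis of fungal nonribosomal peptide
    synthetases (NRPSs) and related adenylating enzymes: position-specific
    profile construction from seed alignments and calibrated local-alignment
    scanning of proteomes, modular domain-architecture annotation (A-T-C
    modules, degenerate adenylation domains, reductase release domains),
    adenylation-domain phylogenies from maximum-likelihood WAG+Gamma pairwise
    distances with neighbor joining and column-bootstrap support, consensus
    subfamily extraction across multiple trees with a reduced-dataset rescue
    rule, Fisher exact tests of subfamily overrepresentation in taxonomic
    groups, and a linear birth-death analysis of gene-family expansion and
    contraction on an ultrametric species tree (transition probabilities,
    pruning likelihoods, global rate estimation, Monte-Carlo family p-values,
    Viterbi ancestral counts and per-branch p-values, parsimony root filter).
    A synthetic-data generator with recorded ground truth exercises every
    stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
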