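Package: alnadd
Title: Add Unaligned Sequences and Fragments into an Existing Multiple
    Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for extending a trusted multiple sequence alignment with
    new sequences without disturbing its existing columns. Full-length
    sequences are added by guide-tree-constrained progressive alignment;
    short fragmentary sequences are placed independently of each other
    against the phylogenetically closest part of the alignment and the
    per-fragment results are merged with corresponding-gap insertion.
    Includes shared 6-mer and Smith-Waterman (affine-gap, Gotoh) distance
    estimation, deterministic UPGMA guide trees with Newick export, a
    profile-profile dynamic-programming engine with a configurable
    terminal-gap policy, a sum-of-pairs alignment-accuracy statistic, a
    profile-alignment baseline, a synthetic benchmark generator that evolves
    sequences along a random tree with substitutions and indels while
    tracking true column homology, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    optparse,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
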