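Package: traitscan
Title: Comparative-Genomics Scanning for Trait-Linked Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for inferring functional partners of a genomic trait by
    comparative genomics: protein homology search by Smith-Waterman local
    alignment with Karlin-Altschul E-values, ortholog assignment by
    bidirectional best hits, phyletic (presence/absence) profiling with
    trait-signature calls for the bacterial Holliday-junction resolution
    system (RuvABC / RuvAB-RecU), gene-neighborhood and operon analysis,
    co-occurrence and combined linkage scoring, progressive multiple
    alignment, Kimura-corrected protein distances, neighbor-joining trees
    with bootstrap support, Fitch parsimony scoring, midpoint-root subtype
    partitioning, and detection of subtype-diagnostic alignment columns.
    Includes a synthetic-genome simulator that plants ground truth (gene
    gain/loss on a species tree, an operon-linked partner, a two-subtype
    protein family) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
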