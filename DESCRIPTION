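Package: symbioscreen
Title: Comparative and Phylogenomic Screening for Candidate Symbiosis Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies candidate symbiosis factors in host-associated bacteria
    by comparative genomics: all-vs-all protein similarity and Markov clustering
    into clusters of orthologous groups (COGs), per-COG neighbor-joining gene
    trees screened for clades occupied exclusively by a designated taxon group
    (with bootstrap support), pan-genome presence/absence comparisons, mobile
    element keyword scans, and fragment-based average nucleotide identity
    (ANIb/APNI) between genome assemblies. Includes a seeded simulator that
    emits genomes, proteomes and annotations with planted group-monophyletic
    gene families so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    igraph,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
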