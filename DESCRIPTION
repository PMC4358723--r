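Package: hgtscan
Title: Detection of Horizontal Gene Transfer from Alignment Bitscore Tables
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects horizontally acquired ('foreign') genes in animal genomes
    from tabular protein-alignment bitscores. Computes the HGT index h (best
    non-metazoan minus best metazoan bitscore) per transcript and gene, builds
    cross-species ortholog groups by Markov clustering of an all-vs-all protein
    similarity graph, assigns the nested HGT confidence classes C, B and A,
    validates candidates by monophyly tests on unrooted taxon-labelled gene
    trees (including a single-tip contamination rescue check), runs genomic
    controls (scaffold linkage to native genes, intron-presence contingency
    tests), performs GO-term enrichment with an enzyme over-representation
    test and a gene-loss control set, and maps founding HGT events onto
    branches of a species tree. A synthetic-study generator with planted truth
    labels makes the whole pipeline testable without sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    igraph,
    phangorn,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
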