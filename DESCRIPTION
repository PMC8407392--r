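Package: panarch
Title: Pan-Genome Openness, Gene Gain-Loss and Lateral Transfer Analysis
    for Reduced Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for collections of small
    prokaryotic genomes such as nanosized, host-associated archaea.
    Implements permutation-based pan/core-genome curves with Heaps-law
    power fits and exponential core-decay fits, Dollo-parsimony ancestral
    gene-content reconstruction with per-branch gain and loss events,
    alignment-free composition-vector phylogeny with neighbor joining,
    average nucleotide identity (ANI) and percentage of conserved
    proteins (POCP) with taxonomic novelty classification, best-hit
    taxonomy calling of putative laterally transferred genes, sequence
    similarity networks with metanode collapsing, and degenerate-primer
    mismatch screening of 16S rRNA genes.  A seeded synthetic-data
    generator evolves gene-family content and sequences on known trees so
    every stage can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    S4Vectors,
    igraph,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
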