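Package: hicratio
Title: Chromatin State Segmentation and Markov Clustering of Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step segmentation of intra-chromosomal Hi-C contact maps.
    A distance-normalized short-range versus long-range interaction ratio is
    computed per genomic bin and its sign partitions each chromosome into
    open ("plus") and closed ("minus") chromatin states; plus-state bins are
    then partitioned into clusters with a deterministic Markov Clustering
    implementation, and cluster boundaries are scored for enrichment of
    functional elements (ChIP-seq peaks, transcription start sites,
    expression tiers) with exact binomial tests, a distance-preserving
    simulated null for within- versus across-cluster interaction counts, and
    two-condition dynamics comparisons. Includes a seeded generator of
    Hi-C-like contact maps with planted states, clusters, and
    boundary-enriched annotation tracks, plus readers and writers for the
    tool's pair, wiggle, BED, and cluster file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
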