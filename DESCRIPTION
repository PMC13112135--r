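Package: loclust
Title: Locus-Level Transcript Clustering from Spliced Genome Alignments
Version: 0.1.0
Authors@R:
    person("Locus", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clusters transcripts from one or more species into single-locus
    clusters using shared overlap of spliced alignments against reference
    genome(s). Exon alignments seed genomic "bins" (de novo or pre-seeded from
    an annotation); transcripts sharing bins are linked in a co-occurrence
    graph whose connected components, after removal of probable fragments
    (one-sided co-occurrence) and chimeras (articulation points), become locus
    clusters. Transcripts that align to no genome are clustered by a greedy
    identity/coverage algorithm. Includes partition-agreement evaluation
    (RI, ARI, NMI, AMI) against reference annotations or ortholog-pair tables,
    locus-level count aggregation for downstream differential expression, and
    a seeded synthetic-data generator with planted loci, isoforms, fragments,
    chimeras and related-genome coordinate drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
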