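Package: pirclust
Title: piRNA Cluster Discovery and Extended 3' UTR Detection from Small RNA Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of 3' UTR-associated PIWI-interacting RNA
    (piRNA) clusters in small-RNA sequencing data. Implements kernel-density
    seeding of read pileups, the two cluster-refinement chains used for testis
    3' UTR and intergenic piRNA clusters, detection of extended 3' UTRs (xUTRs)
    from cluster geometry together with RNA-seq expression against a
    shuffled-intergenic background, detection of the 10-nt 5' overlap
    (ping-pong) signature, somatic 3' UTR small-RNA cluster calling by density
    rules, and classification of somatic clusters as MIWI2-dependent or
    -independent from wild-type/knockout library pairs. A synthetic-data
    generator produces toy genomes, annotations, and read sets with a
    ground-truth manifest so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
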