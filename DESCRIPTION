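Package: deskseq
Title: Desk-Scale RNA-Seq Read Processing, Quality Classification and
    Meta-Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained reimplementation of the per-run decision
    logic used by large-scale uniform RNA-seq processing pipelines:
    quality-encoding detection on a read sample, 3' quality trimming with a
    minimum-length filter, 3' adapter inference by k-mer overrepresentation
    with a genome-absence and frequency clip rule, progressive 5'-end clip
    optimization against unique mapping rate, strandedness calling from
    stranded gene counts, gene and transcript counting, an eight-code
    pass/warn/fail quality classification engine with a
    correlation-to-pass-average metric, transcript-to-gene aggregation,
    reads-per-million normalization, correlation clustering with
    fractional-height tree cuts, and a differential-expression rank
    concordance statistic. A seeded read simulator over generated toy
    references provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: RNASeq, QualityControl, Preprocessing, Clustering
RoxygenNote: 7.3.3
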