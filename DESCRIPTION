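Package: teseq
Title: Repeat-Centric ChIP-seq and RNA-seq Analysis at Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for quantifying protein binding and
    expression at transposable-element (TE) families. Provides peak
    post-processing (summit-centered resizing, replicate-thresholded
    enrichment filtering, genomic-feature categorization), a
    randomized-region bootstrap null for repeat enrichment of peak sets,
    per-family read summation with library-size and exogenous spike-in
    normalization, signal matrices around anchors (waterfall and metaplot)
    and genome bins, stitched LTR-internal-LTR consensus models with an
    ungapped seeded aligner and normalized coverage traces, trimmed-mean
    (TMM) normalization factors, negative-binomial differential testing
    with prior-count stabilized fold changes, and EM fractional assignment
    of multimapping reads. A seed-reproducible synthetic-data module
    generates toy genomes, repeat annotations, ChIP and input fragment sets
    with spike-ins, and negative-binomial count matrices with known ground
    truth, so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
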