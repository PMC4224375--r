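Package: poolctrl
Title: In Silico Pooling of ChIP-seq Input Control Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decides whether multiplexed ChIP-seq input (control) samples can
    be pooled in silico and quantifies the consequences of pooling versus
    per-sample matching controls on peak detection. Provides mapped-read I/O
    (tagAlign/BED6), fragment extension and fixed-width genome binning, seeded
    read subsampling and pooling, a baseline two-sample Poisson peak caller
    with Benjamini-Hochberg control, bin-level Pearson similarity of control
    samples over enriched-region bins with high/low class assignment and a
    pooling recommendation, matched-cost pooling experiment designs (including
    unequal-depth schemes), top-k% rank-overlap sensitivity curves, positive
    predictive value, PWM motif-occurrence scoring with exact p-values, and a
    synthetic read-level ChIP-seq generator with a tunable between-sample
    background correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    mclust,
    ape,
    yaml,
    stats,
    utils,
    tools,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
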