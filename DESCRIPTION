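Package: tcburden
Title: Transcriptomic Burden Estimation, Stratification and Trajectory
    Analysis for Bulk Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders bulk expression matrices along a global transcriptional
    activity axis. Per-sample sums of log2 expression are min-max scaled
    ("median shift") to a transcriptomic burden (TcB) score in [0,1]; samples
    and genes are rearranged by their scores ("abacus" ordering), samples are
    stratified into low/mid/high burden bands, and the bands are compared by
    differential expression, Spearman correlation screening against the burden
    axis, and hypergeometric gene-set over-representation with higher-order
    pathway collapsing. Paired and longitudinal designs are supported through
    burden-shift classification and per-subject burden courses. A synthetic
    data generator with planted gene programs makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
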