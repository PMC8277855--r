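Package: cnvtruth
Title: Exon-Level CNV Truth Sets and Caller Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs exon-level copy-number-variation (CNV) truth sets by
    combining heterogeneous CNV call sets with a beta-binomial Bayes estimator
    under an asymmetric piecewise-linear loss, calibrates the CNV/non-CNV
    decision cutoff against externally validated exons, and benchmarks CNV
    callers against the resulting standard (recall, precision, F1, pairwise
    concordance, confirmation tiers, call-set summaries). A seeded simulator
    of exome models, ground-truth CNV events and heterogeneous call sets
    supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    graphics,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
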