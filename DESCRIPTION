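Package: poolPinpoint
Title: Decoding, Filtering and Benchmarking of Two-Dimensional Overlapped
    Pool Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for double-batched (two-dimensional overlapped) pool
    sequencing experiments, where each DNA sample is placed in exactly one
    row pool and one column pool of an R x C matrix. Provides variant
    normalization and genotype-agnostic set algebra on variant keys,
    construction of theoretical pools and private-variant gold standards
    from per-individual call sets, the pinpointing decoder that assigns
    variants unique to one row pool and one column pool to the individual
    at the intersecting cell, a variant-level simulator of pooled allele
    depths with class-conditional technical annotations, machine-learning
    false-positive filtration with repeated nested cross-validation and
    dual calibrated thresholds, and benchmarking with bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    Biostrings,
    glmnet,
    ranger,
    xgboost,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
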