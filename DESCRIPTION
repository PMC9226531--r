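Package: transposcope
Title: Hierarchical Transposon Classification, Annotation Statistics and
    Transposition-Event Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the computational analysis of transposable elements
    (TEs). Implements a hierarchical random-forest classifier over a
    configurable transposon taxonomy using relative k-mer frequencies and
    binary protein-domain features, with binary and multilabel model
    structures and "all"/"selective" training strategies; hierarchical,
    per-level and per-class evaluation metrics with a stratified
    cross-validation driver; curation rules for assembling a unified
    transposon sequence database from heterogeneous sources; aggregation
    statistics for genome-wide TE annotations (mask construction, TE
    content, class composition, length distributions, density tracks and
    inter-tool overlap); and a structural-variant filtering, deduplication
    and TE-matching pipeline that identifies candidate transposition
    events from long-read SV calls.  Deterministic synthetic-data
    generators make every step testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    randomForest,
    e1071,
    nnet,
    rpart,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
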