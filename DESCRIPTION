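Package: pausepoint
Title: Ribosome Pause Detection and Positional Translatome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Positional analysis of ribosome profiling data in transcript
    space: P-site offset calibration from start-codon metaprofiles,
    per-nucleotide occupancy profiles, detection of ribosome pause sites by
    the 10x peak-over-mean rule and their cross-condition classification
    (induced, resolved, maintained), metagene delta-occupancy profiles over
    5'UTR/CDS/3'UTR, negative-binomial differential translation with joint
    RPF/RNA translational-efficiency categories, preranked permutation GSEA
    with leading-edge concordance between translatome and proteome, and a
    synthetic-data generator with known ground truth so every stage is
    verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    DESeq2,
    fgsea,
    jsonlite,
    Rsamtools,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
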