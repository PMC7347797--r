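Package: cagecascade
Title: CAGE Time-Course Analysis of Promoter and Enhancer Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of dense CAGE (Cap Analysis of Gene Expression) time
    courses of cellular differentiation. Aggregates per-base transcription
    start site (CTSS) tag counts into tag clusters, normalizes samples to a
    common reference power law with expression in tags per million (TPM),
    builds thresholded Pearson co-expression networks partitioned by a
    from-scratch Markov Clustering (MCL) implementation, tests clusters for
    gene-set over/under-representation with exact hypergeometric tails and
    Bonferroni correction, calls candidate enhancers from balanced
    bidirectional transcription with two stringency tiers and annotation
    masks, and infers transcription-factor motif activities with a
    MARA-style ridge regression. Includes a synthetic CAGE time-course
    generator with known ground truth (temporal archetypes, linked eRNA
    pulses, motif design) so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
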