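Package: hmtf
Title: Histone-Modification Signatures at Transcription Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how histone-modification (HM) patterns, flanking DNA
    sequence, and DNA shape discriminate in vivo transcription factor binding
    sites (BSs) from accessibility-matched non-binding exact-motif copies.
    Implements PWM alignment of ChIP-seq peaks with best-hit and dataset
    filters, exact-motif accessibility-matched background construction, per-base
    meta-profiles and the signed differential-HM statistic based on one-sided
    Wilcoxon signed-rank tests with Bonferroni correction, L2-regularized
    multiple linear regression classifiers evaluated by the area under the
    precision-recall curve, leave-one-feature-out deconvolution into binding
    modes, TF pair co-occupancy, and nucleosome-occupancy shift analyses.
    Includes a seeded synthetic-study generator that emulates the assumed data
    structure (implanted motifs, matched accessibility, per-mark HM effect
    sizes, family-shared preferences) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
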