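Package: orfscreen
Title: Hit Calling and Recovery Analysis for ORF-Overexpression Transcriptomic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for open-reading-frame (ORF) overexpression
    expression screens in cell-line models. Normalizes genes-by-samples
    expression matrices to a common log2 scale, anchors experimental batches on
    empty-vector control samples, merges replicate infections into
    condition-level profiles, and calls per-gene HITS as log2 fold-inductions
    against a transcriptome-wide median baseline, Z-scored against a robust
    per-gene estimate of the expected range of variation with a two-tier
    (|Z| > 4 hit, |Z| > 2 suggestive) classification. Includes replicate
    concordance, hypergeometric shared-hit and gene-set overlap statistics,
    a promoter/TF-binding interval intersection utility, and a synthetic-screen
    generator with planted effects for end-to-end verification and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
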