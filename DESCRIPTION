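Package: dsbquant
Title: Quantification of Repair-Factor and DNA:RNA Hybrid Signals at DNA
    Double-Strand Breaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical quantification of signals around DNA double-strand
    breaks (DSBs) from two complementary assays. For two-channel
    single-molecule localization microscopy (SMLM/STORM), the package detects
    per-channel clusters of localizations inside a nucleus region of
    interest, counts cluster overlaps between channels, and normalizes the
    real overlap count by a Monte-Carlo null obtained by randomly
    rearranging the clusters within the nucleus. For DRIP-seq style binned
    coverage, it builds log2 cut/uncut enrichment tracks (RPKM-normalized,
    50-bp bins), aggregates them into distance windows around top-ranked
    nuclease cut sites with a minimum bin-overlap rule, stratifies sites by
    genic context, and applies Wilcoxon signed-rank tests. Percent-input
    normalization, cut/uncut fold induction, and normalizer-relative
    expression for qPCR panels are included, together with synthetic-data
    generators that emulate each assay so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
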