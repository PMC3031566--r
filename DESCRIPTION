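Package: depthCNA
Title: Copy Number Alteration Detection from Depth of Sequencing Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects copy number alterations from the depth of coverage of
    uniquely mapping short sequencing reads, without a matched normal sample.
    Bin counts are modeled with an overdispersed (negative binomial)
    distribution; the smallest bin size satisfying a user-specified false
    discovery rate is selected, together with optimal gain/loss thresholds.
    Counts are corrected for mapability and GC bias (including a
    bisulfite-sequencing-aware effective-GC variant driven by a per-cytosine
    methylation map), segmented by circular binary segmentation, assigned
    absolute copy numbers, and optionally refined against paired-end
    breakpoint calls. Includes a seeded simulation harness measuring
    sensitivity and specificity against seeded alterations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
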