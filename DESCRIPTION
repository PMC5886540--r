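Package: cnvdepth
Title: Depth-of-Coverage Copy Number Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy number variants (CNVs) from binned read-depth
    signals of whole-genome sequencing data. Provides equal-width binning of
    aligned reads with an optimal-bin-size calculator, GC-bias correction
    (median-ratio or loess) and mappability filtering, two change-point
    segmentation engines (exact total-variation minimization with SIC penalty
    selection, and circular binary segmentation with a permutation-calibrated
    t-statistic), threshold-based variant calling with absolute copy number
    estimates, gap merging, BED output, annotation-track overlap with
    priority assignment, and a bin-level simulation framework with
    recall/precision/F-score and breakpoint-error evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    IRanges,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
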