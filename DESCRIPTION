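Package: stat1gof
Title: Transcriptomic Fingerprint Analysis of STAT1 Gain-of-Function Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for dissecting the IFN-gamma response of
    isogenic STAT1 cell lines (wild type and gain-of-function mutants):
    negative-binomial differential-expression calling with median-of-ratios
    normalization and Benjamini-Hochberg correction, cross-condition
    partitioning of regulated genes into common / GOF-shared / private /
    mixed programs, promoter GAS-motif occurrence profiling with exact
    PWM p-value calibration at multiple stringencies, ChIP-seq
    peak/promoter contingency analysis, and the supporting statistics
    (Yates-corrected chi-squared, Friedman with Dunn post hoc,
    many-to-one mean comparisons, error-weighted pathway activation
    Z-scores, PCA with outlier flagging). A synthetic-data generator
    emulates the six-line, two-condition, five-replicate study design with
    planted expression programs, promoter motifs and peaks, so the whole
    pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    DESeq2
Config/testthat/edition: 3
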