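Package: uvbloop
Title: Loop-Design Two-Color Microarray Analysis of UVB Time-Course
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for loop-design two-color spotted microarray
    time courses comparing the UVB response of two cell lines. Provides
    print-tip (pin-wise) lowess normalization of two-channel intensities, a
    per-gene log-linear ANOVA of log-ratios over the hybridization loop with
    per-time-point F tests and Bonferroni-corrected dual-criterion
    differential-expression calls, k-means clustering of 4-point log2
    fold-change patterns, a random-matching null distribution for
    between-line Pearson pattern correlations that yields the most
    discrepant genes, and a local EASE-score (modified one-tailed Fisher)
    gene-set enrichment test. A synthetic-data generator plants known
    differential expression, cluster archetypes and between-line discordant
    genes so that every stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    limma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    MASS,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
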