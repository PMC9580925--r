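Package: juncture
Title: Differential Splice-Junction Expression, Usage and Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression and within-gene differential usage of RNA-seq
    splice junctions from raw junction counts (e.g. STAR SJ.out.tab files).
    Junctions are annotated against a GTF-derived intron index, transformed to
    log2 counts per million with mean-variance observation weights, and tested
    per junction with empirical-Bayes moderated t-statistics. Each junction is
    additionally tested for differential usage relative to the other junctions
    of its gene, classified into interpretable groups (expression-driven,
    usage-driven, or both), and screened for condition-specific neojunctions.
    Further modules associate junction expression with external sample traits
    (correlation, ANOVA, covariate-adjusted linear models), build weighted
    junction co-expression networks (soft thresholding, topological overlap,
    module eigengenes, module-trait correlation) including a 2-pass filter that
    removes gene-expression-driven junction-trait signal, and simulate grouped
    negative-binomial junction counts with known spiked events for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
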