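Package: cfhmc
Title: Cell-Free DNA 5-Hydroxymethylcytosine Profiling Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for plasma cell-free DNA
    5-hydroxymethylcytosine (5hmC) enrichment sequencing: gene-body and
    1kb-bin fragment counting, spike-in enrichment quality control,
    median-of-ratios size-factor normalization, negative-binomial and
    Welch differential 5hmC methylation tests with Benjamini-Hochberg
    correction, hypergeometric gene-set over-representation, per-sample
    gene-set activity scores against a pooled healthy control,
    unsupervised epigenomic subgrouping by hierarchical clustering and
    PCA, progression-free survival analysis (Kaplan-Meier, log-rank,
    Cox proportional hazards, ANCOVA covariate adjustment), and
    longitudinal score dynamics. A bundled negative-binomial cohort
    simulator generates complete synthetic cohorts (counts, fragments,
    spike-ins, sample sheets, survival outcomes) so the whole pipeline
    is testable without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
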