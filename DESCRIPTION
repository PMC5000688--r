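Package: ucmeth
Title: Genome-Wide Promoter Hypermethylation Analysis for Ulcerative Colitis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a genome-wide DNA
    methylation screen for promoter-hypermethylated genes in ulcerative
    colitis. Provides an Infinium-450K-style synthetic data generator
    (beta-distributed methylation states, two probe chemistries, lognormal
    intensities, negative controls, planted case-group effects), array
    preprocessing (background correction from negative controls, detection
    p-values, call-rate QC, beta values, median dye scaling, and a
    three-state beta-mixture quantile normalization of type-II probes onto
    the type-I scale), a differential-methylation filter funnel (pooled-t
    and delta-beta gates, fold-change filter, promoter CpG-island
    selection), sequence-based CpG-island calling and probe annotation,
    unsupervised clustering and classical MDS, validation-layer statistics
    (MSP frequencies, bisulfite clone summaries, Alu-normalized qMSP,
    delta-delta-Ct expression, cohort summaries), and hypergeometric
    gene-set over-representation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
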