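Package: ctPRS
Title: Cell-Type-Specific Polygenic Risk Scores from Single-Cell References
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives cell-type- and neuron-subtype-specific feature sets from
    single-nucleus RNA and ATAC reference matrices, builds the corresponding
    SNP-selection genomic ranges (gene-window, peak-intersection and
    multi-omic strategies, with an APOE-region exclusion), performs variant QC
    and fixed-effects inverse-variance meta-analysis of GWAS summary
    statistics, scores individuals against per-SNP weights restricted to the
    range sets, and runs the endophenotype association battery with a
    multiplicative multiple-testing adjustment, per-SNP follow-up, locus
    window scans and pseudobulk eQTL tests. A synthetic-data module generates
    every input with planted ground truth so the whole pipeline is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
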