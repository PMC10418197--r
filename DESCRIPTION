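Package: atacshare
Title: Cross-Cell-Type Comparison of Chromatin Accessibility Disruption
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical framework for asking whether the same regulatory
    elements lose or gain chromatin accessibility in different cell types of
    the same mutant model. Quantifies overlap between two differential
    ATAC-seq analyses through conditional p-value distributions (Storey pi0)
    with a permutation null, measures sign concordance of effect directions
    with balance-matched resampling, tests collective disruption of a peak
    set with a sampled-set Wilcoxon rank-sum null, profiles disruption
    against CpG-island annotation by p-value decile, and selects regions
    disrupted in all cell types by stepwise within-subset FDR control. A
    synthetic-data module generates multi-cell-type peak universes,
    annotations and negative-binomial count matrices with planted ground
    truth for calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
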