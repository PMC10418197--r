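# atacshare

Cross-cell-type comparison of chromatin-accessibility disruption.

## The problem

Mendelian disorders of the epigenetic machinery (for example Kabuki
syndrome, caused by variants in the histone-modifying enzymes KMT2D or
KDM6A) disrupt chromatin in many cell types at once. A central question
for such disorders is whether the *same* regulatory elements are
disrupted in each affected cell type — which determines, among other
things, whether blood-derived epigenetic signatures can say anything
about what happens in neurons. Given per-cell-type differential
ATAC-seq results (per-peak log2 fold change and p-value), naive
intersection of significant-peak lists answers this badly: it compounds
threshold artifacts and collapses when one analysis is underpowered.

`atacshare` implements a sharper framework:

* **Conditional p-value overlap.** For cell types A and B, select A's
  differential peaks (q < 0.1), find the B peaks overlapping them
  (≥ 1 bp), and estimate the fraction of those that are differential in
  B as 1 − π̂₀ of their B p-values (Storey's estimator: bootstrap over a
  λ grid, with a fixed-λ = 0.5 fallback). Significance comes from
  permutations: random A-peak sets of the same size, scored identically.
  The headline statistic is the ratio observed / mean(null); 1 is the
  null line.
* **Sign concordance.** The proportion of conditional B peaks whose
  log2FC sign matches the overlapping A peak's, against a null that
  redraws A sets with the same size *and* up/down balance — sensitive to
  shared disruption too subtle for any q-value cut.
* **Competitive peak-set tests.** Collective disruption of a designated
  set (e.g. peaks containing epigenetic-clock CpGs) via the rank sum of
  its p-values against sampled same-size sets.
* **CpG-island stratification.** Annotation-overlap proportions per
  p-value decile with Wilson 95% CIs and a logistic deviance-ratio
  summary.
* **Stepwise shared regions.** Regions disrupted in all three cell
  types, applying FDR control *within each conditional subset* — the
  multiplicity burden at steps 2 and 3 is the conditional set, not the
  genome.
* **A synthetic-data module** generating multi-cell-type peak universes,
  annotation tracks, and p-value tables or negative-binomial count
  matrices with planted ground truth (controllable cross-cell-type
  sharing and sign concordance), used by every calibration and power
  test.

## Worked example

Simulate two cell types sharing a 5,000-peak universe, each with 20%
disrupted peaks, half of the first cell type's disrupted peaks also
disrupted in the second (`cross_share = 0.5`) with 90% sign agreement:

```r
library(atacshare)

cfg <- synthetic_config(n_peaks_shared = 5000, n_peaks_specific_per_celltype = 0,
                        frac_disrupted = 0.2, cross_share = 0.5,
                        sign_concordance = 0.9, seed = 2024)
universe <- generate_universe(cfg)
truth    <- assign_truth(universe, cfg)
tabs     <- generate_stats(universe, truth, cfg)

diff_a <- tabs$ct1
set.seed(1)
diff_a$qvalue <- compute_qvalues(diff_a$pvalue)
mm <- match_peaks(universe$cell_types$ct1, universe$cell_types$ct2)

conditional_overlap(diff_a, tabs$ct2, mm, threshold_q = 0.1,
                    n_perm = 1000, seed = 2)
#> Conditional overlap: observed 1-pi0 = 0.5676 over 740 conditional peaks
#>   null mean = 0.2074 (1000 draws), ratio = 2.736, empirical p = 0.000999

sign_concordance(diff_a, tabs$ct2, mm, threshold_q = 0.1,
                 n_perm = 1000, seed = 3)
#> Sign concordance: observed = 0.7135 over 740 conditional peaks (A set: 352 up / 388 down)
#>   null mean = 0.5432, ratio = 1.314, empirical p = 0.000999
```

Reading the output: among the 740 cell-type-2 peaks that overlap
cell-type-1's differential peaks, an estimated 56.8% are themselves
differential, versus 20.7% for random peak sets of the same size — a
ratio of 2.7, far above the null line of 1, with the empirical p at its
permutation floor of 1/1001. The planted sharing is likewise visible as
sign concordance (71.4% same-direction vs 54.3% under the
balance-matched null). With `cross_share = 0` both ratios sit at 1.

The `analysis/` directory holds numbered driver scripts
(`01_simulate.R` … `05_shared_regions.R`) that run the full workflow on
a three-cell-type simulation — differential summaries, pairwise
overlap/concordance, peak-set and decile profiles, and stepwise shared
regions — writing tables under `results/`. Real data enter through
`read_bed()` (BED3/6, narrowPeak), `read_differential()` (TSV:
`peak_id, log2FC, pvalue`), count matrices with a sample sheet, or the
`run_pipeline()` config interface.

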