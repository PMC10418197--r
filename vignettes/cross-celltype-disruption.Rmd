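---
title: "Comparing chromatin-accessibility disruption across cell types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing chromatin-accessibility disruption across cell types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(atacshare)
```

## The question and the statistical framework

When the same germline variant in an epigenetic regulator disrupts
chromatin in several cell types, are the *same* regulatory elements
affected? Differential ATAC-seq analyses run separately in each cell type
give per-peak effect sizes (log2 fold changes) and p-values, but naive
intersection of significant-peak lists answers the question badly: it
inherits every threshold artifact and has low power when one analysis is
underpowered. This package implements a framework built instead on
conditional p-value distributions:

1. **Conditional overlap.** Take the differential peaks of cell type A
   (q-value < 0.1), find the cell-type-B peaks overlapping them (at least
   1 bp), and estimate the fraction of *those* that are differential in B
   as $1 - \hat\pi_0$ of their B p-values, where $\hat\pi_0$ is Storey's
   estimate of the true-null proportion. If disruption were unrelated
   between the cell types, this conditional fraction would equal the
   fraction for randomly chosen A peaks. Significance therefore comes
   from a permutation null: random A-peak sets of the same size, mapped
   to B and scored identically. The headline statistic is the ratio of
   the observed fraction to the mean of the null fractions; 1 is the null
   line.
2. **Sign concordance.** Ignoring significance in B entirely, the
   proportion of conditional B peaks whose log2 fold change has the same
   sign as the overlapping A peak. The permutation null redraws A sets
   with the same size *and* the same up/down split, so a globally skewed
   direction of change cannot masquerade as concordance. This view is far
   more sensitive to subtle shared disruption than any q-value cut.
3. **Peak-set disruption.** For a designated set (e.g. peaks containing
   epigenetic-clock CpGs), the sum of the ranks of the set's p-values
   among all peaks, compared with sampled same-size sets: a competitive
   test that detects collective disruption even when no individual peak
   stands out. Observed rank sums *below* the null indicate disruption,
   hence the one-sided default.
4. **Annotation profiles.** The proportion of peaks overlapping an
   annotation (CpG islands) per p-value decile, with Wilson 95% binomial
   confidence intervals, summarised by the deviance ratio
   $1 - D_{res}/D_{null}$ of a logistic regression of the overlap flag on
   the raw p-value.
5. **Stepwise shared regions.** Regions disrupted in all three cell
   types: start from cell type 1's differential peaks, then apply FDR
   control *within the conditional subset* in cell type 2, then again in
   cell type 3. Computing q-values within the subset — whose
   multiplicity burden is hundreds of peaks, not the genome — is what
   makes the procedure sensitive; it is deliberately not the same as
   intersecting three genome-wide q < 0.1 lists.

## $\pi_0$ estimation

`estimate_pi0()` provides the plug-in estimator
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$ and the Storey
(2002) bootstrap: evaluate the plug-in on the grid
$\lambda \in \{0.05, \dots, 0.95\}$, estimate each grid point's MSE
around $\min_\lambda \hat\pi_0(\lambda)$ from 100 bootstrap resamples,
and report the estimate at the MSE-minimising $\lambda$. Because
$\hat\pi_0(\lambda)$ depends on the p-values only through their counts in
the $\lambda$-grid bins, the resampling is implemented as a multinomial
draw over bin counts — distribution-identical to resampling the p-values
and fast enough to sit inside 10,000-draw permutation loops. The
production cascade (`conditional_overlap()`, within-subset q-values)
tries the bootstrap first and falls back to the fixed-$\lambda = 0.5$
plug-in when the bootstrap cannot produce a finite MSE; subsets below 20
p-values fall back further to $\pi_0 = 1$, i.e. plain
Benjamini–Hochberg, with a warning.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold_q` | 0.1 | FDR level defining "differential" at every selection step |
| `min_overlap` | 1 bp | interval-overlap convention throughout |
| `flank` | 2000 bp | promoter half-width around a TSS (strand-symmetric) |
| `n_perm` (overlap) | 10,000 | permutation draws for the overlap null |
| `n_perm` (concordance, peak set) | 1,000 | permutation draws for those nulls |
| `lambda` | 0.5 | fixed-$\lambda$ fallback tuning value |
| `min_median` | 10 | count filter: peaks with median count below this are dropped |
| `bottom_frac` | 0.05 | gene-level differential flag: bottom 5% of aggregated p-values |

Empirical p-values use the add-one correction
$(1 + \#\{null \ge obs\})/(1 + n_{perm})$ and can never be exactly 0; the
smallest attainable value is $1/(n_{perm}+1)$.

## The built-in differential test

The per-peak test in `simple_de_test()` is intentionally simple:
median-of-ratios library-size normalisation, log2 fold change between
normalised group means with a pseudo-count of 0.5, and a pooled-variance
two-sample statistic on $\log_2(\text{normalised count} + 0.5)$ referred
to a Student-t null with $n_1 + n_2 - 2$ degrees of freedom. The t
reference is the standard normal-theory choice at the 4–8 samples per
group typical of these designs; an N(0,1) reference would reject at
roughly 8–9% under the null at df = 8 and break the package's own
calibration contract. The test is a transparent stand-in, not a
reimplementation of a negative-binomial GLM with surrogate-variable
adjustment: analyses of real data should import an externally fitted
differential table via `read_differential()`, whose schema
(`peak_id, log2FC, pvalue[, qvalue, baseMean]`) is the package's exchange
format. On import, q-values are recomputed from the p-values over all
imported peaks, which also covers tables where an upstream tool set some
adjusted p-values to NA through independent filtering.

`downsample_counts()` implements read-depth reduction as binomial
thinning of the count matrix, which is distributionally equivalent to
subsampling unique reads before counting.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` + `generate_universe()` / `assign_truth()` /
`generate_stats()` / `generate_counts()` produce a multi-cell-type study
with known ground truth:

* cell types share `n_peaks_shared` peaks with identical coordinates and
  ids plus private peaks, mirroring analyses restricted to peaks detected
  in both cell types;
* each cell type has a planted disrupted subset (default 20% of the
  universe); for the designated pair, `cross_share` controls forced
  sharing (0 = fully independent draws, 1 = identical disrupted sets
  when quotas match) and `sign_concordance` the probability of equal
  effect signs on jointly disrupted peaks;
* fast mode draws p-values directly — Uniform(0,1) for nulls,
  Beta($a$, 1) with $a = 0.1$ for disrupted peaks, chosen because its
  closed-form tail $P(p > t) = 1 - t^a$ gives analytic oracles for every
  $\pi_0$ recovery test; counts mode draws negative-binomial counts
  (dispersion 0.1) whose expected value is multiplied by $2^{lfc}$ in
  mutant samples;
* annotation structure: 12% of peaks at promoters, CpG islands at 60% of
  promoter peaks with a 2.43-fold higher count baseline (the ratio of
  across-peak median normalised counts seen between B cells and neurons
  in sorted-cell ATAC data), a clock-CpG track of width-1 positions in
  1% of peaks, and 5 samples per genotype with |log2FC| centred at 0.5
  — changes mostly below 2-fold, as observed in this setting.

Each cell type and stage draws from a named RNG substream of the master
seed, so adding a cell type or toggling a pipeline stage never perturbs
the other draws, and all outputs are byte-reproducible from the config.

The generator intentionally omits several features of real ATAC-seq
data: peaks are non-overlapping and evenly spaced (so a promoter window
touches exactly one peak), there is no GC or fragment-length bias, no
correlation between neighbouring peaks, no surrogate confounders, and
annotation tracks are independent of the planted disruption unless the
test constructs the dependence itself. Passing calibration and recovery
tests on this generator therefore validates the *statistical machinery*
— estimator identities, null calibration, power under planted sharing —
not robustness to the technical artifacts a real study must handle
upstream.

## Numerical and design choices

* **Coordinates** are 0-based half-open (BED) everywhere; 1-based inputs
  must be converted at the reader boundary.
* **Promoter windows are strand-independent** since the ±2 kb flank is
  symmetric; strand is retained for provenance.
* **Multi-overlap handling:** a B peak overlapped by several
  A-differential peaks enters the conditional set once; for sign
  comparison it is paired with the overlapping A peak with the smallest
  A p-value, ties broken by id — a deterministic rule where several are
  defensible.
* **Ratio denominator:** the mean (not median) of the null fractions;
  when the null mean is exactly 0 the ratio is reported as NaN with a
  warning and the empirical p remains valid.
* **Zero log2 fold changes** are excluded from concordance counts with a
  warning rather than arbitrarily signed.
* **Wilson intervals** for the decile profile, for better coverage at
  proportions near 0 or 1 than the Wald form.
* **Deviance ratio** uses the raw p-value as the single linear predictor
  of a logistic model; constant flags short-circuit to 0.
* **Bottom-5% gene rule:** a strict count quantile
  (`floor(0.05 * n_genes)`) with ties broken by gene id, so exactly 5 of
  100 genes are flagged regardless of ties.
* **Null sets for the rank-sum test** are drawn from the same analysis
  universe as the target set (promoter-only universe for promoter sets);
  covariate-matched sampling (e.g. by mean count) is a recognised
  extension that is not implemented.
* **Degenerate inputs:** empty peak sets and empty annotation tracks are
  legal (all-false flags); an empty step-1 selection, an all-covered
  blacklist, and a conditional set below 20 p-values raise informative
  errors rather than returning unstable estimates.

## Problem sizes used in the checks

The test suite runs its calibration loops at universes of 2,000–20,000
peaks with 99–200 permutation draws and 8–200 replicates per contract,
and the power and recovery checks at 10,000 peaks — sizes chosen so the
full suite completes in about a minute while keeping the Monte-Carlo
error of each rejection-rate estimate well inside the asserted bands.
The acceptance script runs the overlap-ratio null calibration at its
stated design: 50,000 shared peaks, 20% independently disrupted per cell
type, 200 permutations, 20 replicates.

## Known limitations

* The built-in differential test assumes approximate log-normality of
  normalised counts within groups; it is not a substitute for a
  dispersion-moderated NB fit on real data.
* $1-\hat\pi_0$ is an estimator with its own bias (the fixed-$\lambda$
  form is conservative when alternatives have mass above $\lambda$), so
  conditional overlap fractions should be compared against their
  permutation nulls, not read as absolute fractions.
* The stepwise procedure's within-subset q-values control FDR at each
  step conditionally; the composed three-step selection does not carry a
  single global FDR guarantee.
* With universes below a few hundred peaks the permutation nulls become
  coarse (the empirical p has resolution $1/(n_{perm}+1)$) and the
  $\pi_0$ cascade falls back to BH more often.
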