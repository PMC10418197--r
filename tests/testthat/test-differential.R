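test_that("filter_median_count applies the strict 'median < threshold' rule", {
  counts <- rbind(a = c(9, 9, 11), b = c(10, 10, 10), c = c(50, 60, 70))
  expect_equal(filter_median_count(counts, 10), c("b", "c"))
  expect_equal(filter_median_count(counts, 0), c("a", "b", "c"))
  expect_error(filter_median_count(matrix(nrow = 0, ncol = 3)), "empty")
})

test_that("simple_de_test is exact on identical groups and recovers planted effects", {
  half <- withr::with_seed(1, matrix(rnbinom(200 * 3, mu = 100, size = 10),
                                     nrow = 200))
  counts <- cbind(half, half)   # mutant samples literally equal wild-type
  rownames(counts) <- paste0("p", 1:200)
  groups <- rep(c("wildtype", "mutant"), each = 3)
  de <- simple_de_test(counts, groups, reference = "wildtype")
  expect_equal(de$log2FC, rep(0, 200))
  expect_equal(de$pvalue, rep(1, 200))

  # 4-fold increase planted in 10% of peaks, low dispersion, n = 5/group:
  # log2FC lands within +/-0.3 of 2 for at least 95% of planted peaks
  m <- 2000
  planted <- seq_len(200)
  mu <- matrix(100, m, 10)
  mu[planted, 6:10] <- 400
  counts2 <- withr::with_seed(2, matrix(
    rnbinom(length(mu), mu = mu, size = 100), nrow = m,
    dimnames = list(paste0("p", 1:m), NULL)))
  de2 <- simple_de_test(counts2, rep(c("wildtype", "mutant"), each = 5),
                        reference = "wildtype")
  expect_gt(mean(abs(de2$log2FC[planted] - 2) <= 0.3), 0.95)
  # normalization keeps unplanted peaks near zero (median-of-ratios shifts
  # slightly when all planted changes point the same way)
  expect_lt(abs(mean(de2$log2FC[-planted])), 0.1)
  expect_error(simple_de_test(counts2[, c(1, 6, 7)], c("wildtype", "mutant",
                                                       "mutant")),
               "at least 2 samples")
})

test_that("simple_de_test is calibrated under the global null", {
  m <- 10000
  counts <- withr::with_seed(3, matrix(
    rnbinom(m * 10, mu = 150, size = 10), nrow = m,   # dispersion 0.1
    dimnames = list(paste0("p", 1:m), NULL)))
  de <- simple_de_test(counts, rep(c("wildtype", "mutant"), each = 5),
                       reference = "wildtype")
  # p approximately Uniform(0,1)
  expect_gt(suppressWarnings(ks.test(de$pvalue, "punif"))$p.value, 0.01)
  # type-I error at nominal 0.05 within [0.03, 0.07]
  rate <- mean(de$pvalue < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("compute_qvalues matches hand-computed values and the BH oracle", {
  expect_equal(compute_qvalues(c(0.01, 0.5, 1.0), pi0 = 1),
               c(0.03, 0.75, 1.0))
  expect_equal(compute_qvalues(c(0.2, 0.9), pi0 = 0), c(0, 0))
  p <- withr::with_seed(4, c(runif(500), rbeta(100, 0.1, 1)))
  q <- compute_qvalues(p, pi0 = 1)
  expect_equal(q, p.adjust(p, "BH"))   # independent BH implementation
  # monotone in p, clamped to [0, 1]
  o <- order(p)
  expect_true(all(diff(q[o]) >= 0))
  expect_true(all(q >= 0 & q <= 1))
  expect_error(compute_qvalues(numeric(0)), "empty")
})

test_that("aggregate_gene_p takes per-gene minima and flags the bottom 5%", {
  # gene g1 has peaks with p = 0.4 and 0.02 -> gene p 0.02; g_none absent
  tss <- data.frame(gene_id = paste0("g", 1:100), chrom = "chrS",
                    position = (1:100) * 6000L + 250L, strand = "+")
  promoters <- make_promoters(tss, 2000L)
  peaks <- peak_set(rep("chrS", 101),
                    c((1:100) * 6000L, 1L) + 100L,
                    c((1:100) * 6000L, 1L) + 600L,
                    paste0("pk", 1:101))
  p <- withr::with_seed(5, runif(101))
  p[1] <- 0.4
  diff <- data.frame(peak_id = peaks$id, pvalue = p)
  # add a second, smaller-p peak on g1's promoter
  peaks2 <- rbind(as.data.frame(peaks),
                  data.frame(chrom = "chrS", start = 6100L, end = 6200L,
                             id = "pk_extra"))
  class(peaks2) <- c("peak_set", "data.frame")
  diff2 <- rbind(diff, data.frame(peak_id = "pk_extra", pvalue = 0.02))
  gt <- aggregate_gene_p(diff2, peaks2, promoters)
  expect_equal(gt$pvalue[gt$gene_id == "g1"], 0.02)
  # peak 101 sits far from every promoter: no gene for it, and a gene with
  # no overlapping peak is absent
  expect_equal(nrow(gt), 100L)
  # exactly 5 of 100 genes flagged differential
  expect_equal(sum(gt$differential), 5L)
  expect_equal(gt$gene_id[gt$differential], gt$gene_id[order(gt$pvalue)][1:5])
})

test_that("downsample_counts is exact binomial thinning", {
  counts <- matrix(c(0L, 10L, 10000L, 7L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_identical(downsample_counts(counts, 1), counts)
  big <- matrix(10000L, 200, 5)
  th <- downsample_counts(big, 0.25, seed = 6)
  # cellwise binomial moments: mean 2500, sd sqrt(10000*.25*.75) ~ 43.3
  expect_lt(abs(mean(th) - 2500), 43.3 / sqrt(1000) * 4)
  expect_lt(abs(sd(as.vector(th)) - 43.3), 5)
  # total sum scales by ~0.25
  expect_lt(abs(sum(th) / sum(big) - 0.25), 0.0025)
  expect_identical(downsample_counts(big, 0.25, seed = 6), th)
  expect_error(downsample_counts(big, 0), "fraction")
})

test_that("differential tables round-trip; import recomputes q from p", {
  f <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(peak_id = paste0("p", 1:50),
                  log2FC = withr::with_seed(7, rnorm(50)),
                  pvalue = withr::with_seed(8, runif(50)))
  write_differential(d, f)
  d2 <- read_differential(f)
  expect_equal(d2$pvalue, d$pvalue)
  # q-values recomputed from p over all imported peaks: valid, monotone in p
  expect_true(all(d2$qvalue >= 0 & d2$qvalue <= 1))
  expect_true(all(diff(d2$qvalue[order(d2$pvalue)]) >= 0))
  expect_error(read_differential(withr::local_tempfile(fileext = ".x")),
               "cannot open|No such file|missing")
})

test_that("downsampled null counts show no CpG-decile association", {
  # null synthetic counts, thinned to 25%: the CpG-decile deviance ratio
  # stays at noise level (< 0.01)
  cfg <- synthetic_config(n_peaks_shared = 4000,
                          n_peaks_specific_per_celltype = 0,
                          frac_disrupted = 0, frac_promoter = 0.3,
                          frac_cpg_island_among_promoters = 0.6,
                          n_samples_per_group = 4, seed = 20)
  u <- generate_universe(cfg)
  cm <- generate_counts(u, assign_truth(u, cfg), cfg)$ct1
  thin <- downsample_counts(cm$counts, 0.25, seed = 21)
  keep <- filter_median_count(thin, 10)
  de <- simple_de_test(thin[keep, , drop = FALSE], cm$groups,
                       reference = "wildtype")
  flags <- annotate(u$cell_types$ct1[match(keep, u$cell_types$ct1$id), ],
                    u$tracks$cpg_island)
  dp <- decile_profile(de, flags)
  expect_lt(dp$deviance_ratio, 0.01)
})
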