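test_that("estimate_pi0 matches closed forms and recovers mixtures", {
  # clamping: all p = 1 gives raw 2, clamped to 1
  expect_equal(estimate_pi0(rep(1, 100), method = "fixed_lambda")$pi0, 1)
  expect_equal(estimate_pi0(rep(0.001, 100), method = "fixed_lambda")$pi0, 0)
  # 70% Uniform + 30% Beta(0.1, 1) at lambda = 0.5: analytic expectation
  # (0.7*0.5 + 0.3*(1 - 0.5^0.1)) / 0.5 = 0.740
  p <- withr::with_seed(31, c(runif(7000), rbeta(3000, 0.1, 1)))
  est <- estimate_pi0(p, method = "fixed_lambda", lambda = 0.5)
  expect_lt(abs(est$pi0 - 0.740), 0.03)
  # bootstrap estimator lands within 0.05 of the true pi0 = 0.7
  boot <- withr::with_seed(32, estimate_pi0(p, method = "bootstrap"))
  expect_false(boot$failed)
  expect_lt(abs(boot$pi0 - 0.7), 0.05)
  # input validation
  expect_error(estimate_pi0(runif(10)), "at least 20")
  expect_error(estimate_pi0(c(runif(30), NaN)), "NA/NaN")
})

test_that("estimate_pi0 on pure uniforms returns >= 0.9 for both methods", {
  p <- withr::with_seed(33, runif(10000))
  expect_gte(estimate_pi0(p, method = "fixed_lambda")$pi0, 0.9)
  expect_gte(withr::with_seed(34, estimate_pi0(p, method = "bootstrap"))$pi0,
             0.9)
})

test_that("conditional_overlap recovers the planted conditional mixture", {
  # conditional set constructed as a 60/40 Uniform/Beta(0.1,1) mixture:
  # expected 1 - pi0 at lambda 0.5 is 1 - 0.654 = 0.346
  m <- 10000
  ids <- paste0("pk", 1:m)
  a_sel <- 2000
  withr::with_seed(41, {
    b_p <- runif(m)
    alt <- sample.int(a_sel, 0.4 * a_sel)
    b_p[alt] <- rbeta(length(alt), 0.1, 1)
  })
  cond_p <- b_p[seq_len(a_sel)]
  est <- estimate_pi0(cond_p, method = "fixed_lambda", lambda = 0.5)
  expect_lt(abs((1 - est$pi0) - 0.346), 0.05)

  # the full permutation machinery sees the planted overlap
  diff_A <- data.frame(peak_id = ids, log2FC = 0, pvalue = 0.5,
                       qvalue = c(rep(0.01, a_sel), rep(0.9, m - a_sel)))
  diff_B <- data.frame(peak_id = ids, log2FC = 0, pvalue = b_p)
  ov <- conditional_overlap(diff_A, diff_B, identity_match(ids),
                            n_perm = 99, seed = 42)
  expect_equal(ov$n_conditional_peaks, a_sel)
  expect_gt(ov$ratio, 1)
  expect_equal(ov$empirical_p, 1 / 100)   # add-one lower bound
  expect_true(all(ov$null_fracs >= 0 & ov$null_fracs <= 1))
})

test_that("conditional_overlap handles degenerate and error cases", {
  ids <- paste0("pk", 1:200)
  diff_A <- data.frame(peak_id = ids, log2FC = 0, pvalue = 0.5,
                       qvalue = c(rep(0.01, 50), rep(0.9, 150)))
  # B p-values all 1: observed and null fractions collapse to 0, the ratio
  # is NaN with a warning, and the empirical p stays valid
  diff_B <- data.frame(peak_id = ids, log2FC = 0, pvalue = rep(1, 200))
  expect_warning(
    ov <- conditional_overlap(diff_A, diff_B, identity_match(ids),
                              n_perm = 19, seed = 1),
    "ratio undefined")
  expect_true(is.nan(ov$ratio))
  expect_gt(ov$empirical_p, 0)
  expect_lte(ov$empirical_p, 1)

  # no A peak passes the threshold
  diff_A2 <- transform(diff_A, qvalue = 0.9)
  expect_error(conditional_overlap(diff_A2, diff_B, identity_match(ids)),
               "threshold")
  # too few conditional p-values
  diff_A3 <- transform(diff_A, qvalue = c(rep(0.01, 5), rep(0.9, 195)))
  expect_error(conditional_overlap(diff_A3, diff_B, identity_match(ids)),
               "conditional")
})

test_that("multi-overlap peaks are deduplicated and direction-symmetric", {
  # A query spanning two subjects contributes each subject once; with
  # identical-coordinate universes the mapping direction cannot matter
  cfg <- synthetic_config(n_peaks_shared = 2000,
                          n_peaks_specific_per_celltype = 0,
                          frac_disrupted = 0.2, cross_share = 0.5, seed = 43)
  u <- generate_universe(cfg)
  st <- generate_stats(u, assign_truth(u, cfg), cfg)
  d1 <- st$ct1
  d1$qvalue <- withr::with_seed(44, compute_qvalues(d1$pvalue))
  m_fwd <- match_peaks(u$cell_types$ct1, u$cell_types$ct2)
  m_rev_raw <- match_peaks(u$cell_types$ct2, u$cell_types$ct1)
  # invert the reverse map
  inv <- split(rep(names(m_rev_raw), lengths(m_rev_raw)),
               unlist(m_rev_raw, use.names = FALSE))
  inv <- lapply(inv, sort)
  fwd <- m_fwd[lengths(m_fwd) > 0]
  nm <- sort(names(fwd))
  expect_equal(fwd[nm], inv[nm])
  ov1 <- conditional_overlap(d1, st$ct2, fwd, n_perm = 49, seed = 45)
  ov2 <- conditional_overlap(d1, st$ct2, inv[names(fwd)], n_perm = 49,
                             seed = 45)
  expect_equal(ov1$observed_frac, ov2$observed_frac)
  expect_equal(ov1$null_fracs, ov2$null_fracs)
})

test_that("sign_concordance is calibrated and detects planted concordance", {
  m <- 4000
  ids <- paste0("pk", 1:m)
  # B signs are fair coins independent of A: observed ~ 0.5, ratio ~ 1
  withr::with_seed(51, {
    a_lfc <- rnorm(m)
    b_lfc <- rnorm(m)
  })
  diff_A <- data.frame(peak_id = ids, log2FC = a_lfc, pvalue = 0.5,
                       qvalue = c(rep(0.01, 400), rep(0.9, m - 400)))
  diff_B <- data.frame(peak_id = ids, log2FC = b_lfc, pvalue = 0.5)
  sc <- sign_concordance(diff_A, diff_B, identity_match(ids),
                         n_perm = 199, seed = 52)
  expect_lt(abs(sc$observed_prop - 0.5), 0.08)
  expect_lt(abs(sc$ratio - 1), 0.15)
  expect_gt(sc$empirical_p, 0.01)

  # perfect planted concordance: observed 1, minimal empirical p
  cfg <- synthetic_config(n_peaks_shared = 2000,
                          n_peaks_specific_per_celltype = 0,
                          frac_disrupted = 0.2, cross_share = 1,
                          sign_concordance = 1, seed = 53)
  u <- generate_universe(cfg)
  tr <- assign_truth(u, cfg)
  st <- generate_stats(u, tr, cfg)
  # evaluate concordance on the truly disrupted A set itself
  d1 <- st$ct1
  d1$qvalue <- ifelse(d1$peak_id %in% tr$ct1$peak_id, 0.01, 0.9)
  ids2 <- u$cell_types$ct1$id
  sc2 <- sign_concordance(d1, st$ct2, identity_match(ids2),
                          n_perm = 99, seed = 54)
  expect_equal(sc2$observed_prop, 1)
  expect_gt(sc2$ratio, 1)
  expect_equal(sc2$empirical_p, 1 / 100)
})

test_that("balance-matched nulls keep the ratio at 1 under sign imbalance", {
  # 80/20 up/down imbalance in both tables, no association: across
  # replicates the mean ratio stays near 1
  ratios <- vapply(1:8, function(r) {
    m <- 3000
    ids <- paste0("pk", 1:m)
    withr::with_seed(60 + r, {
      a_lfc <- abs(rnorm(m)) * sample(c(1, -1), m, TRUE, prob = c(0.8, 0.2))
      b_lfc <- abs(rnorm(m)) * sample(c(1, -1), m, TRUE, prob = c(0.8, 0.2))
      qv <- sample(c(rep(0.01, 300), rep(0.9, m - 300)))
    })
    diff_A <- data.frame(peak_id = ids, log2FC = a_lfc, pvalue = 0.5,
                         qvalue = qv)
    diff_B <- data.frame(peak_id = ids, log2FC = b_lfc, pvalue = 0.5)
    sign_concordance(diff_A, diff_B, identity_match(ids),
                     n_perm = 99, seed = 70 + r)$ratio
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.05)
})
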