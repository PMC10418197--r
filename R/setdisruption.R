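# Collective disruption of a designated peak set, and disruption profiles
# across annotation strata.

#' Competitive rank-sum test of a peak set against a sampled-set null
#'
#' The observed statistic W is the sum of the ranks of the set's p-values
#' among all p-values in the universe (average ranks for ties); a set of
#' collectively disrupted peaks has small p-values and therefore a small W.
#' The null distribution comes from sampling `n_perm` uniformly random id
#' sets of the same size from the universe and recomputing W. The default
#' one-sided empirical p asks whether W is lower than expected under the
#' null; a two-sided variant is available.
#'
#' @param diff differential table (`peak_id`, `pvalue`) defining the
#'   analysis universe. Draw the universe to match the target set's
#'   context (e.g. promoter peaks only when testing a promoter set).
#' @param set_ids peak ids of the designated set; a subset of the universe,
#'   with 2 <= size < universe size.
#' @param n_perm sampled null sets (default 1000).
#' @param seed integer seed.
#' @param alternative `"less"` (default, collective disruption) or
#'   `"two_sided"`.
#' @return list of class `peakset_test`: `W_observed`, `null_W`,
#'   `empirical_p_low` (or two-sided `empirical_p`), `set_size`,
#'   `universe_size`.
#' @export
peakset_ranksum_test <- function(diff, set_ids, n_perm = 1000L, seed = 1L,
                                 alternative = c("less", "two_sided")) {
  alternative <- match.arg(alternative)
  m <- nrow(diff)
  set_ids <- unique(set_ids)
  if (!length(set_ids)) stop("empty peak set")
  if (!all(set_ids %in% diff$peak_id))
    stop("set contains ids outside the universe")
  k <- length(set_ids)
  if (k < 2L) stop("set must contain at least 2 peaks")
  if (k >= m) stop("set must be smaller than the universe")
  r <- rank(diff$pvalue)            # average ranks for ties
  idx <- match(set_ids, diff$peak_id)
  W <- sum(r[idx])
  null_W <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sum(r[sample.int(m, k)]), 0))
  p_low <- (1 + sum(null_W <= W)) / (1 + n_perm)
  res <- list(W_observed = W, null_W = null_W, set_size = k,
              universe_size = m, alternative = alternative,
              empirical_p_low = p_low)
  if (alternative == "two_sided") {
    p_high <- (1 + sum(null_W >= W)) / (1 + n_perm)
    res$empirical_p <- min(1, 2 * min(p_low, p_high))
  }
  class(res) <- "peakset_test"
  res
}

#' @export
print.peakset_test <- function(x, ...) {
  cat(sprintf(paste0(
    "Peak-set rank-sum test: W = %.1f (set %d of %d peaks)\n",
    "  null mean W = %.1f; one-sided (low) empirical p = %.4g\n"),
    x$W_observed, x$set_size, x$universe_size, mean(x$null_W),
    x$empirical_p_low))
  if (!is.null(x[["empirical_p"]]))
    cat(sprintf("  two-sided empirical p = %.4g\n", x[["empirical_p"]]))
  invisible(x)
}

wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Annotation-overlap profile across p-value deciles
#'
#' Peaks are ranked by p-value (ascending) and split into 10 equal-size
#' bins (any remainder goes to the earliest bins). Per decile, the
#' proportion of peaks carrying the annotation flag is reported with a
#' Wilson 95% binomial confidence interval. The association strength over
#' the whole range is summarised as the deviance ratio 1 - residual/null
#' deviance of a logistic regression of the flag on the raw p-value; 0
#' means no relationship.
#'
#' @param diff differential table with `peak_id`, `pvalue` (>= 10 peaks).
#' @param flags logical vector aligned with `diff` rows (e.g. CpG-island
#'   overlap from [annotate()]).
#' @return list of class `decile_profile`: `profile` (data.frame with
#'   decile, n_peaks, n_overlapping, proportion, ci_low, ci_high) and
#'   `deviance_ratio`.
#' @export
decile_profile <- function(diff, flags) {
  m <- nrow(diff)
  if (m < 10L) stop("need at least 10 peaks for a decile profile")
  if (length(flags) != m) stop("flags not aligned with the table")
  o <- order(diff$pvalue)
  f <- flags[o]
  base <- m %/% 10L; rem <- m %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, rem), rep(0L, 10L - rem))
  dec <- rep(seq_len(10L), times = sizes)
  n_ov <- tapply(f, dec, sum)
  ci <- t(mapply(wilson_ci, n_ov, sizes))
  prof <- data.frame(decile = 1:10, n_peaks = sizes,
                     n_overlapping = as.integer(n_ov),
                     proportion = as.numeric(n_ov) / sizes,
                     ci_low = ci[, 1], ci_high = ci[, 2])
  dr <- if (length(unique(flags)) < 2L) 0 else {
    fit <- suppressWarnings(stats::glm(flags ~ diff$pvalue,
                                       family = stats::binomial()))
    if (fit$null.deviance <= 0) 0 else
      max(0, min(1, 1 - fit$deviance / fit$null.deviance))
  }
  structure(list(profile = prof, deviance_ratio = dr),
            class = "decile_profile")
}

#' @export
print.decile_profile <- function(x, ...) {
  cat("Annotation overlap by p-value decile (deviance ratio =",
      format(x$deviance_ratio, digits = 3), ")\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Per-stratum p-value summaries
#'
#' For each stratum of a categorical peak annotation: size, median
#' p-value, fraction of p < 0.05, and the estimated differential fraction
#' 1 - pi0 (fixed lambda = 0.5; undefined below 20 peaks). Each
#' non-reference stratum is also compared to the reference stratum with a
#' two-sided Wilcoxon rank-sum test on the p-values.
#'
#' @param diff differential table.
#' @param strata character/factor labels aligned with `diff` rows.
#' @param reference reference stratum label (default: first level).
#' @return data.frame, one row per stratum, with `ranksum_W` and
#'   `ranksum_p` filled for non-reference strata when more than one
#'   stratum is present.
#' @export
stratified_p_summary <- function(diff, strata, reference = NULL) {
  strata <- as.character(strata)
  if (length(strata) != nrow(diff)) stop("strata not aligned with table")
  if (anyNA(strata)) stop("every peak must be labelled")
  lev <- unique(strata)
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop("reference stratum not present")
  p_ref <- diff$pvalue[strata == reference]
  rows <- lapply(lev, function(s) {
    ps <- diff$pvalue[strata == s]
    frac_diff <- if (length(ps) >= 20L)
      1 - estimate_pi0(ps, method = "fixed_lambda", lambda = 0.5)$pi0
    else NA_real_
    wt <- if (s != reference && length(lev) > 1L) {
      w <- stats::wilcox.test(ps, p_ref)
      c(unname(w$statistic), w$p.value)
    } else c(NA_real_, NA_real_)
    data.frame(stratum = s, n = length(ps), median_p = stats::median(ps),
               frac_p_below_05 = mean(ps < 0.05), frac_differential = frac_diff,
               ranksum_W = wt[1], ranksum_p = wt[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Direction of accessibility change within a peak set
#'
#' Counts and proportions of positive / negative log2 fold changes within
#' the designated set, plus quantiles of the set's log2FC distribution.
#'
#' @param diff differential table with `log2FC`.
#' @param set_ids non-empty subset of the universe's peak ids.
#' @return list: `n`, `n_positive`, `n_negative`, `n_zero`,
#'   `prop_positive`, `prop_negative`, `lfc_quantiles`.
#' @export
direction_of_change <- function(diff, set_ids) {
  set_ids <- unique(set_ids)
  if (!length(set_ids)) stop("empty peak set")
  if (!all(set_ids %in% diff$peak_id))
    stop("set contains ids outside the universe")
  lfc <- diff$log2FC[match(set_ids, diff$peak_id)]
  list(n = length(lfc),
       n_positive = sum(lfc > 0), n_negative = sum(lfc < 0),
       n_zero = sum(lfc == 0),
       prop_positive = mean(lfc > 0), prop_negative = mean(lfc < 0),
       lfc_quantiles = stats::quantile(lfc, c(0.05, 0.25, 0.5, 0.75, 0.95)))
}
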