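# Conditional p-value overlap and sign concordance between two
# differential accessibility analyses run in different cell types.

select_differential <- function(diff, threshold_q) {
  if (is.null(diff$qvalue)) stop("differential table lacks q-values; ",
                                 "run compute_qvalues() first")
  diff$peak_id[diff$qvalue < threshold_q]
}

map_to_subject <- function(a_ids, match) {
  unique(unlist(match[a_ids], use.names = FALSE))
}

#' Conditional p-value overlap between two cell types
#'
#' Measures whether peaks disrupted in cell type A are preferentially
#' disrupted in cell type B. The A-differential peaks (q < `threshold_q`)
#' are mapped through `match` to the overlapping B peaks, and the fraction
#' of those that are truly differential is estimated as 1 - pi0 of their
#' B p-values (bootstrap pi0 with fixed-lambda 0.5 fallback). Significance
#' comes from a permutation null: `n_perm` random A-peak sets of the same
#' size, drawn uniformly without replacement from the shared universe, are
#' mapped and scored identically. The headline statistic is the ratio of
#' the observed fraction to the mean of the null fractions; 1 means no
#' more shared disruption than expected by chance.
#'
#' @param diff_A differential table for the conditioning cell type; must
#'   carry q-values.
#' @param diff_B differential table for the evaluated cell type.
#' @param match mapping from A peak ids to overlapping B peak ids, as
#'   produced by [match_peaks()] on the shared peak universe.
#' @param threshold_q q-value cutoff defining A's differential peaks
#'   (default 0.1).
#' @param n_perm permutation draws (default 10000).
#' @param seed integer seed for the permutations.
#' @param min_conditional minimum number of conditional B p-values
#'   (default 20).
#' @return list of class `overlap_result`: `observed_frac`, `null_fracs`,
#'   `ratio` (NaN with a warning when the null mean is 0), `empirical_p`
#'   (add-one corrected, never 0), `n_conditional_peaks`, `n_a_selected`,
#'   `threshold_q`, `n_perm`, `seed`.
#' @export
conditional_overlap <- function(diff_A, diff_B, match, threshold_q = 0.1,
                                n_perm = 10000L, seed = 1L,
                                min_conditional = 20L) {
  a_sel <- select_differential(diff_A, threshold_q)
  if (!length(a_sel))
    stop("no cell-type-A peaks pass q < ", threshold_q,
         "; raise the threshold")
  universe <- intersect(names(match), diff_A$peak_id)
  a_sel <- intersect(a_sel, universe)
  b_p <- stats::setNames(diff_B$pvalue, diff_B$peak_id)

  cond_ids <- map_to_subject(a_sel, match)
  cond_p <- b_p[intersect(cond_ids, names(b_p))]
  if (length(cond_p) < min_conditional)
    stop("only ", length(cond_p), " conditional B p-values (< ",
         min_conditional, ")")
  # observed estimate and permutation draws share the one seeded stream so
  # a call is fully reproducible from its seed
  drawn <- with_seed(seed, {
    obs <- 1 - pi0_cascade(cond_p)$pi0
    nf <- vapply(seq_len(n_perm), function(i) {
      ids <- sample(universe, length(a_sel))
      pp <- b_p[intersect(map_to_subject(ids, match), names(b_p))]
      pi0 <- pi0_for_null(pp)
      if (is.na(pi0)) NA_real_ else 1 - pi0
    }, 0)
    list(obs = obs, nf = nf)
  })
  observed <- drawn$obs
  null_fracs <- drawn$nf

  ok <- !is.na(null_fracs)
  if (!all(ok)) warning(sum(!ok), " permutation draw(s) had too few ",
                        "conditional p-values and were dropped")
  nf <- null_fracs[ok]
  mean_null <- mean(nf)
  ratio <- if (mean_null == 0) {
    warning("mean null fraction is 0; ratio undefined (NaN)")
    NaN
  } else observed / mean_null
  res <- list(observed_frac = observed, null_fracs = nf, ratio = ratio,
              empirical_p = (1 + sum(nf >= observed)) / (1 + length(nf)),
              n_conditional_peaks = length(cond_p),
              n_a_selected = length(a_sel),
              threshold_q = threshold_q, n_perm = n_perm, seed = seed)
  class(res) <- "overlap_result"
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Conditional overlap: observed 1-pi0 = %.4f over %d conditional peaks\n",
    "  null mean = %.4f (%d draws), ratio = %.3f, empirical p = %.4g\n"),
    x$observed_frac, x$n_conditional_peaks, mean(x$null_fracs),
    length(x$null_fracs), x$ratio, x$empirical_p))
  invisible(x)
}

# For each conditional B peak, the overlapping selected A peak with the
# smallest A p-value (deterministic pairing for sign comparison).
pair_b_to_a <- function(a_ids, match, a_p) {
  hits <- match[a_ids]
  b <- unlist(hits, use.names = FALSE)
  if (!length(b)) return(character(0))
  a <- rep(a_ids, lengths(hits))
  o <- order(a_p[a], a)           # ties broken by A id
  b <- b[o]; a <- a[o]
  keep <- !duplicated(b)
  stats::setNames(a[keep], b[keep])
}

#' Sign concordance of accessibility changes between two cell types
#'
#' Among B peaks overlapping A's differential peaks, the proportion whose
#' log2 fold change has the same sign as the overlapping A peak's
#' (each B peak is compared against the overlapping A-differential peak
#' with the smallest A p-value). The permutation null redraws A-peak sets
#' of identical size *and* identical up/down sign split from the shared
#' universe, so an imbalanced sign composition cannot inflate the ratio.
#' Conditional peaks with a log2FC of exactly 0 (in A or B) are excluded
#' with a warning.
#'
#' @inheritParams conditional_overlap
#' @param n_perm permutation draws (default 1000).
#' @return list of class `concordance_result`: `observed_prop`,
#'   `null_props`, `ratio`, `empirical_p`, `n_conditional_peaks`,
#'   `n_up`, `n_down`, `threshold_q`, `n_perm`, `seed`.
#' @export
sign_concordance <- function(diff_A, diff_B, match, threshold_q = 0.1,
                             n_perm = 1000L, seed = 1L,
                             min_conditional = 20L) {
  a_sel <- select_differential(diff_A, threshold_q)
  if (!length(a_sel)) stop("no cell-type-A peaks pass q < ", threshold_q)
  universe <- intersect(names(match), diff_A$peak_id)
  a_sel <- intersect(a_sel, universe)
  a_p <- stats::setNames(diff_A$pvalue, diff_A$peak_id)
  a_sign <- stats::setNames(sign(diff_A$log2FC), diff_A$peak_id)
  b_sign <- stats::setNames(sign(diff_B$log2FC), diff_B$peak_id)

  score <- function(ids) {
    pairing <- pair_b_to_a(ids, match, a_p)
    b <- intersect(names(pairing), names(b_sign))
    sa <- a_sign[pairing[b]]; sb <- b_sign[b]
    use <- sa != 0 & sb != 0
    if (!sum(use)) return(c(prop = NA_real_, n = 0))
    c(prop = mean(sa[use] == sb[use]), n = sum(use))
  }

  obs <- score(a_sel)
  if (obs[["n"]] < min_conditional)
    stop("only ", obs[["n"]], " sign-comparable conditional peaks (< ",
         min_conditional, ")")
  n_pairs <- pair_b_to_a(a_sel, match, a_p)
  n_dropped <- length(n_pairs) - obs[["n"]]
  if (n_dropped > 0)
    warning(n_dropped, " conditional peak(s) with log2FC exactly 0 excluded")

  n_up <- sum(a_sign[a_sel] > 0)
  n_down <- sum(a_sign[a_sel] < 0)
  pool_up <- universe[a_sign[universe] > 0]
  pool_down <- universe[a_sign[universe] < 0]
  if (length(pool_up) < n_up || length(pool_down) < n_down)
    stop("universe cannot supply a balance-matched null draw")

  null_props <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ids <- c(if (n_up) sample(pool_up, n_up) else character(),
             if (n_down) sample(pool_down, n_down) else character())
    score(ids)[["prop"]]
  }, 0))
  np <- null_props[!is.na(null_props)]
  mean_null <- mean(np)
  ratio <- if (mean_null == 0) NaN else obs[["prop"]] / mean_null
  res <- list(observed_prop = obs[["prop"]], null_props = np, ratio = ratio,
              empirical_p = (1 + sum(np >= obs[["prop"]])) / (1 + length(np)),
              n_conditional_peaks = obs[["n"]], n_up = n_up, n_down = n_down,
              threshold_q = threshold_q, n_perm = n_perm, seed = seed)
  class(res) <- "concordance_result"
  res
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Sign concordance: observed = %.4f over %d conditional peaks ",
    "(A set: %d up / %d down)\n",
    "  null mean = %.4f, ratio = %.3f, empirical p = %.4g\n"),
    x$observed_prop, x$n_conditional_peaks, x$n_up, x$n_down,
    mean(x$null_props), x$ratio, x$empirical_p))
  invisible(x)
}

#' Summarise an overlap or concordance result for reporting
#'
#' @param x an `overlap_result` or `concordance_result`.
#' @return one-row data.frame with the observed statistic, null summary
#'   quantiles, ratio and empirical p.
#' @export
overlap_report <- function(x) {
  nulls <- x$null_fracs %||% x$null_props
  qs <- stats::quantile(nulls, c(0.025, 0.5, 0.975))
  data.frame(observed = x$observed_frac %||% x$observed_prop,
             null_mean = mean(nulls), null_q025 = qs[[1]],
             null_median = qs[[2]], null_q975 = qs[[3]],
             ratio = x$ratio, empirical_p = x$empirical_p,
             n_conditional = x$n_conditional_peaks,
             threshold_q = x$threshold_q, n_perm = x$n_perm, seed = x$seed)
}
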