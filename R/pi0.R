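#' Estimate the proportion of true nulls (pi0) from p-values
#'
#' Two estimators of Storey's pi0. `fixed_lambda` is the plug-in
#' `min(1, #\{p > lambda\} / (m * (1 - lambda)))`. `bootstrap` evaluates
#' the plug-in on the grid lambda = 0.05, 0.10, ..., 0.95, estimates the
#' mean squared error of each grid estimate around `min_lambda pi0(lambda)`
#' from 100 bootstrap resamples of the p-values, and returns the estimate
#' at the MSE-minimising lambda (Storey 2002). The bootstrap is carried out
#' by multinomial resampling of the lambda-grid bin counts, which induces
#' the same distribution on every `pi0(lambda)` as resampling individual
#' p-values. 1 - pi0 estimates the fraction of truly differential features.
#'
#' @param p numeric p-values in \[0, 1\], at least 20 of them.
#' @param method `"bootstrap"` (default) or `"fixed_lambda"`.
#' @param lambda tuning threshold for `fixed_lambda` (default 0.5).
#' @param n_boot bootstrap resamples (default 100).
#' @return list of class `pi0_estimate`: `pi0` (clamped to \[0,1\]),
#'   `lambda_used`, `method`, and `failed` (`TRUE` when no grid point had a
#'   finite bootstrap MSE, signalling that a fallback estimator is needed).
#' @export
estimate_pi0 <- function(p, method = c("bootstrap", "fixed_lambda"),
                         lambda = 0.5, n_boot = 100L) {
  method <- match.arg(method)
  if (anyNA(p) || any(!is.finite(p))) stop("p-values contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  m <- length(p)
  if (m < 20L) stop("need at least 20 p-values to estimate pi0, got ", m)

  if (method == "fixed_lambda") {
    if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
    pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
    res <- list(pi0 = max(0, pi0), lambda_used = lambda,
                method = "fixed_lambda", failed = FALSE)
  } else {
    grid <- seq(0.05, 0.95, by = 0.05)
    # bin counts between consecutive grid points; tail sums give #{p > lambda}
    bins <- tabulate(findInterval(p, grid) + 1L, nbins = length(grid) + 1L)
    tail_counts <- rev(cumsum(rev(bins)))[-1L]          # #{p > lambda_j}
    pi0_grid <- pmin(1, tail_counts / (m * (1 - grid)))
    target <- min(pi0_grid)
    draws <- stats::rmultinom(n_boot, m, prob = pmax(bins, 0) / m)
    tails <- apply(draws, 2L, function(cnt) rev(cumsum(rev(cnt)))[-1L])
    pi0_boot <- pmin(tails / (m * (1 - grid)), 1)       # grid x n_boot
    mse <- rowMeans((pi0_boot - target)^2)
    if (!any(is.finite(mse))) {
      res <- list(pi0 = NA_real_, lambda_used = NA_real_,
                  method = "bootstrap", failed = TRUE)
    } else {
      j <- which.min(mse)
      res <- list(pi0 = max(0, min(1, pi0_grid[j])), lambda_used = grid[j],
                  method = "bootstrap", failed = FALSE)
    }
  }
  class(res) <- "pi0_estimate"
  res
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("pi0 = %.4f (method %s, lambda %s)\n", x$pi0, x$method,
              format(x$lambda_used)))
  invisible(x)
}

# Bootstrap pi0 with fixed-lambda(0.5) fallback on bootstrap failure.
pi0_cascade <- function(p, lambda = 0.5) {
  est <- estimate_pi0(p, method = "bootstrap")
  if (isTRUE(est$failed)) est <- estimate_pi0(p, method = "fixed_lambda",
                                              lambda = lambda)
  est
}

# Internal minimal pi0 for permutation nulls: same cascade but tolerant of
# small conditional sets (falls back to pi0 = 1 below min_n p-values).
pi0_for_null <- function(p, min_n = 20L) {
  if (length(p) < min_n) return(NA_real_)
  pi0_cascade(p)$pi0
}
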