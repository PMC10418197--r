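# Seed plumbing: every stochastic entry point takes an integer seed and
# evaluates under it without disturbing the caller's RNG state. Named
# substreams derived from one master seed keep the stages of a pipeline
# independent: enabling or disabling one stage never changes another's
# draws.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic integer sub-seed below 2^31 for a named stream.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) %% 1e6) * 2099 + (h %% 1e6) + 7L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage of tested features called disrupted
#'
#' Small reporting helper: the share of tested regulatory elements called
#' differentially accessible, as a percentage rounded to one decimal
#' (the convention used in run summaries).
#'
#' @param n_disrupted number of features passing the FDR threshold.
#' @param n_tested number of features tested.
#' @return percentage, one decimal.
#' @export
disruption_percentage <- function(n_disrupted, n_tested) {
  if (n_tested <= 0) stop("n_tested must be positive")
  round(100 * n_disrupted / n_tested, 1)
}
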