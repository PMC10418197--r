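# Shared fixture builders. Everything is generated in code; no stored data.

# Identity match on a set of ids (shared universe with identical
# coordinates maps each peak to itself).
identity_match <- function(ids) stats::setNames(as.list(ids), ids)

# A pair of differential tables over a shared universe of m peaks:
# each cell type independently has frac_dis of peaks disrupted with
# Beta(beta_a, 1) p-values, the rest Uniform(0, 1); log2FC is the planted
# sign times |N(0.5, 0.25)| for disrupted peaks and N(0, 0.05) noise
# otherwise. Used for calibration loops where the full universe generator
# would be overkill.
make_independent_pair <- function(m, frac_dis = 0.2, beta_a = 0.1,
                                  seed = 1L) {
  withr::with_seed(seed, {
    ids <- paste0("peak_", seq_len(m))
    one <- function() {
      dis <- sample.int(m, round(frac_dis * m))
      p <- stats::runif(m)
      p[dis] <- stats::rbeta(length(dis), beta_a, 1)
      lfc <- stats::rnorm(m, 0, 0.05)
      lfc[dis] <- sample(c(-1, 1), length(dis), TRUE) *
        abs(stats::rnorm(length(dis), 0.5, 0.25))
      data.frame(peak_id = ids, log2FC = lfc, pvalue = p,
                 stringsAsFactors = FALSE)
    }
    list(A = one(), B = one())
  })
}

# Small random peak sets for overlap oracles.
random_peak_set <- function(n, seed, chroms = c("chr1", "chr2"),
                            span = 5000L, max_w = 400L, prefix = "p") {
  withr::with_seed(seed, {
    start <- sample.int(span, n, replace = TRUE)
    w <- sample.int(max_w, n, replace = TRUE)
    peak_set(sample(chroms, n, replace = TRUE), start, start + w,
             paste0(prefix, seq_len(n)))
  })
}

# O(n*m) brute-force interval matcher; the oracle match_peaks must agree
# with.
brute_force_match <- function(query, subject, min_overlap = 1L) {
  out <- lapply(seq_len(nrow(query)), function(i) {
    hit <- vapply(seq_len(nrow(subject)), function(j) {
      if (query$chrom[i] != subject$chrom[j]) return(FALSE)
      inter <- min(query$end[i], subject$end[j]) -
        max(query$start[i], subject$start[j])
      inter >= min_overlap
    }, TRUE)
    sort(subject$id[hit])
  })
  stats::setNames(out, query$id)
}
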