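#' Filter peaks by median count
#'
#' Keeps peaks whose median count across all samples is at least
#' `min_median`; peaks with median below the threshold are excluded
#' (the rule is strictly "less than", so a median exactly at the
#' threshold is retained).
#'
#' @param counts peak-by-sample integer matrix with peak ids as rownames.
#' @param min_median minimum median count (default 10).
#' @return character vector of retained peak ids.
#' @export
filter_median_count <- function(counts, min_median = 10) {
  if (is.null(dim(counts)) || nrow(counts) == 0L) stop("empty count matrix")
  med <- apply(counts, 1L, stats::median)
  rownames(counts)[med >= min_median]
}

# DESeq-style median-of-ratios size factors.
size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) stop("no peak has all-positive counts; cannot normalize")
  sf <- apply(counts, 2L, function(cl) exp(stats::median(log(cl[use]) - logg[use])))
  sf
}

#' Simple two-group differential accessibility test
#'
#' A deliberately simple per-peak test for count matrices: samples are
#' normalized by median-of-ratios size factors, the log2 fold change is
#' taken between normalized group means (pseudo-count 0.5), and a two-sided
#' p-value comes from a pooled-variance two-sample statistic on
#' log2(normalized count + 0.5), referred to a Student-t null with
#' n1 + n2 - 2 degrees of freedom. It is a transparent stand-in for a full
#' negative-binomial GLM fit; externally produced differential tables can
#' be imported with [read_differential()] instead.
#'
#' @param counts peak-by-sample matrix, already filtered
#'   (see [filter_median_count()]).
#' @param groups character/factor of length `ncol(counts)` with two levels;
#'   the first level alphabetically is the reference unless `reference`
#'   is given.
#' @param reference label of the baseline (wild-type) group.
#' @return a differential table: data.frame with `peak_id`, `log2FC`
#'   (non-reference vs reference), `pvalue`, `baseMean` (mean normalized
#'   count). q-values are added separately with [compute_qvalues()].
#' @export
simple_de_test <- function(counts, groups, reference = NULL) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("groups must have exactly 2 levels")
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop("reference level not in groups")
  other <- setdiff(lev, reference)
  i1 <- which(groups == other)      # e.g. mutant
  i0 <- which(groups == reference)  # e.g. wildtype
  if (length(i1) < 2L || length(i0) < 2L)
    stop("each group needs at least 2 samples")

  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  y <- log2(norm + 0.5)
  m1 <- rowMeans(y[, i1, drop = FALSE])
  m0 <- rowMeans(y[, i0, drop = FALSE])
  v1 <- apply(y[, i1, drop = FALSE], 1L, stats::var)
  v0 <- apply(y[, i0, drop = FALSE], 1L, stats::var)
  n1 <- length(i1); n0 <- length(i0)
  df <- n1 + n0 - 2L
  s2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n0))
  stat <- ifelse(se > 0, (m1 - m0) / se, 0)
  p <- 2 * stats::pt(-abs(stat), df = df)
  p[se == 0] <- 1

  data.frame(
    peak_id = rownames(counts),
    log2FC = log2(rowMeans(norm[, i1, drop = FALSE]) + 0.5) -
      log2(rowMeans(norm[, i0, drop = FALSE]) + 0.5),
    pvalue = p,
    baseMean = rowMeans(norm),
    stringsAsFactors = FALSE)
}

#' Storey q-values
#'
#' `q_i = min over thresholds t >= p_i of pi0 * m * t / max(1, #\{p <= t\})`,
#' clamped to \[0, 1\] and monotone in p. With `pi0 = 1` this reduces
#' exactly to Benjamini-Hochberg adjusted p-values. When `pi0` is not
#' supplied it is estimated by the bootstrap method with fixed-lambda(0.5)
#' fallback (see [estimate_pi0()]).
#'
#' @param p numeric p-values in \[0, 1\].
#' @param pi0 optional proportion of true nulls overriding the estimate.
#' @return numeric q-values aligned with `p`.
#' @export
compute_qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  if (is.null(pi0)) pi0 <- pi0_cascade(p)$pi0
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / pmax(1, m:1)))[ro]
  q
}

#' Aggregate peak p-values to genes via promoter overlap
#'
#' Each gene's p-value is the minimum over the differential peaks that
#' overlap any of its promoter windows (>= 1 bp). Genes whose promoters
#' overlap no analyzed peak are absent from the result. Genes whose
#' aggregated p-value falls in the bottom `bottom_frac` (default 5%) are
#' flagged differential; the cut is a strict count quantile with ties
#' broken by gene id so the flag is deterministic.
#'
#' @param diff differential table with `peak_id` and `pvalue`.
#' @param peaks [peak_set()] giving coordinates for the `peak_id`s.
#' @param promoters promoter [peak_set()] from [make_promoters()] (carries
#'   a `gene_id` column).
#' @param bottom_frac fraction of genes to flag (default 0.05).
#' @return data.frame `gene_id`, `pvalue`, `differential`.
#' @export
aggregate_gene_p <- function(diff, peaks, promoters, bottom_frac = 0.05) {
  peaks <- peaks[peaks$id %in% diff$peak_id, , drop = FALSE]
  mp <- match_peaks(promoters, peaks)
  pmap <- stats::setNames(diff$pvalue, diff$peak_id)
  gene_for <- stats::setNames(promoters$gene_id, promoters$id)
  rows <- Filter(function(x) length(x$peaks) > 0L,
                 lapply(names(mp), function(pid)
                   list(gene = gene_for[[pid]], peaks = mp[[pid]])))
  if (!length(rows))
    return(data.frame(gene_id = character(), pvalue = numeric(),
                      differential = logical()))
  gp <- vapply(rows, function(x) min(pmap[x$peaks]), 0)
  gene <- vapply(rows, function(x) x$gene, "")
  agg <- tapply(gp, gene, min)
  out <- data.frame(gene_id = names(agg), pvalue = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$gene_id), , drop = FALSE]
  n_flag <- floor(nrow(out) * bottom_frac)
  out$differential <- seq_len(nrow(out)) <= n_flag
  rownames(out) <- NULL
  out
}

#' Binomial thinning of a count matrix
#'
#' Replaces each count by a Binomial(count, fraction) draw, the matrix
#' analogue of downsampling a library to a fraction of its reads.
#' `fraction = 1` returns the input unchanged.
#'
#' @param counts non-negative integer matrix.
#' @param fraction retention probability in (0, 1\].
#' @param seed integer seed for the thinning draws.
#' @return thinned matrix with the same dimnames.
#' @export
downsample_counts <- function(counts, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(counts)
  out <- with_seed(seed, matrix(
    stats::rbinom(length(counts), size = as.vector(counts), prob = fraction),
    nrow = nrow(counts), dimnames = dimnames(counts)))
  out
}

#' Read / write differential tables
#'
#' TSV with header `peak_id, log2FC, pvalue` and optional `qvalue`,
#' `baseMean`; this is also the import format for externally computed
#' differential results (e.g. a DESeq2 fit). On import, q-values are
#' recomputed from the p-values over all imported peaks unless
#' `keep_qvalues = TRUE`.
#'
#' @param path file path.
#' @param keep_qvalues reuse an imported `qvalue` column instead of
#'   recomputing (default `FALSE`).
#' @return data.frame differential table.
#' @export
read_differential <- function(path, keep_qvalues = FALSE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("peak_id", "log2FC", "pvalue")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("differential table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$pvalue < 0 | d$pvalue > 1, na.rm = TRUE))
    stop("pvalue outside [0, 1]")
  if (!keep_qvalues || is.null(d$qvalue))
    d$qvalue <- compute_qvalues(d$pvalue)
  d
}

#' @rdname read_differential
#' @param diff differential table to write.
#' @export
write_differential <- function(diff, path) {
  utils::write.table(diff, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
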