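# Stepwise selection of regions disrupted in every cell type, and gene-set
# enrichment between the resulting sets.

# Within-subset q-values: pi0 cascade when the subset is large enough,
# otherwise plain BH (pi0 = 1) with a warning.
subset_qvalues <- function(p, min_n = 20L) {
  if (length(p) < min_n) {
    warning("subset of ", length(p), " p-values too small for pi0; ",
            "using pi0 = 1 (Benjamini-Hochberg)")
    return(compute_qvalues(p, pi0 = 1))
  }
  compute_qvalues(p, pi0 = pi0_cascade(p)$pi0)
}

#' Stepwise cross-cell-type selection of disrupted regions
#'
#' Starts from cell type 1's differential peaks (q < `q_threshold`), maps
#' them to overlapping cell type 2 peaks, and re-applies FDR control
#' *within that conditional subset*: q-values at steps 2 and 3 are
#' computed from the subset's p-values only, which is what gives the
#' procedure its sensitivity — the multiplicity burden is the size of the
#' conditional set, not the genome. Step 3 repeats the operation on cell
#' type 3 within the step-2 survivors.
#'
#' @param diff_1 differential table with q-values (cell type 1).
#' @param diff_2,diff_3 differential tables with p-values.
#' @param match_12 mapping cell-type-1 ids -> overlapping cell-type-2 ids.
#' @param match_23 mapping cell-type-2 ids -> overlapping cell-type-3 ids.
#' @param q_threshold FDR level at every step (default 0.1).
#' @param seed integer seed for the bootstrap pi0 estimation inside the
#'   within-subset q-value computations; with it the selection is fully
#'   deterministic.
#' @return list of class `stepwise_result`: `step1_ids`, `step2_ids`,
#'   `step3_ids` (each in its own cell type's id space; step3 within step2
#'   within step1 through the mappings), per-step conditional tables
#'   `step2_table`, `step3_table` (`peak_id`, `pvalue`, `qvalue`), and
#'   `q_threshold`.
#' @export
stepwise_select <- function(diff_1, diff_2, diff_3, match_12, match_23,
                            q_threshold = 0.1, seed = 1L) {
  step1 <- select_differential(diff_1, q_threshold)
  if (!length(step1)) stop("no step-1 peaks at q < ", q_threshold)

  cond_step <- function(prev_ids, match, diff_next, stream) {
    ids <- map_to_subject(prev_ids, match)
    ids <- intersect(ids, diff_next$peak_id)
    p <- diff_next$pvalue[match(ids, diff_next$peak_id)]
    tab <- data.frame(peak_id = ids, pvalue = p, stringsAsFactors = FALSE)
    if (nrow(tab))
      tab$qvalue <- with_seed(substream_seed(seed, stream),
                              subset_qvalues(tab$pvalue))
    tab
  }
  step2_tab <- cond_step(step1, match_12, diff_2, "step2")
  step2 <- step2_tab$peak_id[step2_tab$qvalue < q_threshold]
  step3_tab <- if (length(step2))
    cond_step(step2, match_23, diff_3, "step3") else
    data.frame(peak_id = character(), pvalue = numeric(), qvalue = numeric())
  step3 <- step3_tab$peak_id[step3_tab$qvalue < q_threshold]

  structure(list(step1_ids = step1, step2_ids = step2, step3_ids = step3,
                 step2_table = step2_tab, step3_table = step3_tab,
                 q_threshold = q_threshold),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Stepwise selection at q < %s: %d -> %d -> %d regions\n"),
    format(x$q_threshold), length(x$step1_ids), length(x$step2_ids),
    length(x$step3_ids)))
  invisible(x)
}

#' Fold enrichment of one gene set within another
#'
#' Fold enrichment is the observed-over-expected overlap
#' `(|A intersect B| / |A|) / (|B| / |universe|)`; significance is the
#' two-sided Fisher exact test on the 2x2 membership table. The universe
#' must be given explicitly — the fold depends strongly on it.
#'
#' @param set_A,set_B non-empty gene id vectors, subsets of `universe`.
#' @param universe gene id vector defining the background.
#' @return list of class `enrichment_result`: `table` (2x2 matrix),
#'   `fold_enrichment`, `fisher_p`.
#' @export
gene_set_enrichment <- function(set_A, set_B, universe) {
  set_A <- unique(set_A); set_B <- unique(set_B); universe <- unique(universe)
  if (!length(set_A) || !length(set_B)) stop("empty gene set")
  if (!all(set_A %in% universe) || !all(set_B %in% universe))
    stop("gene sets must be subsets of the universe")
  n <- length(universe)
  ab <- length(intersect(set_A, set_B))
  a_only <- length(set_A) - ab
  b_only <- length(set_B) - ab
  neither <- n - ab - a_only - b_only
  tab <- matrix(c(ab, a_only, b_only, neither), nrow = 2,
                dimnames = list(A = c("in_A", "not_A"),
                                B = c("in_B", "not_B")))
  fold <- (ab / length(set_A)) / (length(set_B) / n)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  structure(list(table = tab, fold_enrichment = fold, fisher_p = ft$p.value),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Gene-set enrichment: fold = %.1f, Fisher p = %.3g\n",
              x$fold_enrichment, x$fisher_p))
  print(x$table)
  invisible(x)
}

#' Is double disruption more predictive than single disruption?
#'
#' Compares the estimated differential fraction (1 - pi0, fixed
#' lambda = 0.5) of cell type 3's p-values conditional on regions passing
#' step 2 (disrupted in cell types 1 and 2) versus regions passing step 1
#' only (disrupted in cell type 1 but not 2). A positive difference means
#' regions disrupted in both upstream cell types are more likely to be
#' disrupted in the third.
#'
#' @param step a [stepwise_select()] result.
#' @param diff_3 cell type 3's differential table.
#' @param match_23 mapping cell-type-2 ids -> cell-type-3 ids.
#' @param min_n minimum conditional set size (default 20); below it the
#'   corresponding fraction is `NA` with a warning.
#' @return list: `frac_both`, `frac_single`, `difference`, `n_both`,
#'   `n_single`.
#' @export
conditional_enrichment_check <- function(step, diff_3, match_23,
                                         min_n = 20L) {
  p3 <- stats::setNames(diff_3$pvalue, diff_3$peak_id)
  cond_frac <- function(ids2) {
    ids3 <- intersect(map_to_subject(ids2, match_23), names(p3))
    if (length(ids3) < min_n) {
      warning("conditional set of ", length(ids3),
              " peaks (< ", min_n, "); fraction undefined")
      return(c(NA_real_, length(ids3)))
    }
    c(1 - estimate_pi0(p3[ids3], method = "fixed_lambda")$pi0, length(ids3))
  }
  both <- cond_frac(step$step2_ids)
  single_ids <- setdiff(step$step2_table$peak_id, step$step2_ids)
  single <- cond_frac(single_ids)
  list(frac_both = both[1], frac_single = single[1],
       difference = both[1] - single[1],
       n_both = as.integer(both[2]), n_single = as.integer(single[2]))
}
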