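# End-to-end orchestration: one config, reproducible seeds, staged outputs.

#' Validate a pipeline run configuration
#'
#' A run config is a list with:
#' \itemize{
#'   \item `cell_types`: named list; per cell type either `differential`
#'     (TSV path) or both `counts` and `samples` (TSV paths), plus `peaks`
#'     (BED path).
#'   \item `annotations`: optional paths `cpg_island`, `clock_cpg`,
#'     `blacklist`, `tss`.
#'   \item `analyses`: character subset of `overlap`, `concordance`,
#'     `peakset`, `decile`, `stepwise`.
#'   \item `q_threshold` (default 0.1), `n_perm_overlap` (default 10000),
#'     `n_perm_concordance` / `n_perm_peakset` (default 1000),
#'     `seed` (default 1), `out_dir`.
#' }
#'
#' @param config list as above.
#' @return the config with defaults filled in; errors name every invalid
#'   field before any computation runs.
#' @export
validate_run_config <- function(config) {
  errs <- character()
  if (is.null(config$cell_types) || length(config$cell_types) < 2L)
    errs <- c(errs, "cell_types: need at least 2")
  for (ct in names(config$cell_types)) {
    spec <- config$cell_types[[ct]]
    has_diff <- !is.null(spec$differential)
    has_counts <- !is.null(spec$counts) && !is.null(spec$samples)
    if (!has_diff && !has_counts)
      errs <- c(errs, paste0(ct, ": needs 'differential' or ",
                             "'counts'+'samples'"))
    for (f in c("differential", "counts", "samples", "peaks")) {
      pth <- spec[[f]]
      if (!is.null(pth) && !file.exists(pth))
        errs <- c(errs, paste0(ct, "$", f, ": file not found: ", pth))
    }
  }
  for (f in c("cpg_island", "clock_cpg", "blacklist", "tss")) {
    pth <- config$annotations[[f]]
    if (!is.null(pth) && !file.exists(pth))
      errs <- c(errs, paste0("annotations$", f, ": file not found: ", pth))
  }
  config$q_threshold <- config$q_threshold %||% 0.1
  if (config$q_threshold <= 0 || config$q_threshold >= 1)
    errs <- c(errs, "q_threshold: must be in (0, 1)")
  if (length(errs)) stop("invalid run config:\n  ",
                         paste(errs, collapse = "\n  "))
  config$analyses <- config$analyses %||%
    c("overlap", "concordance", "peakset", "decile", "stepwise")
  config$n_perm_overlap <- config$n_perm_overlap %||% 10000L
  config$n_perm_concordance <- config$n_perm_concordance %||% 1000L
  config$n_perm_peakset <- config$n_perm_peakset %||% 1000L
  config$seed <- config$seed %||% 1L
  config$out_dir <- config$out_dir %||% "atacshare_run"
  config
}

load_cell_type <- function(spec) {
  diff <- if (!is.null(spec$differential)) {
    read_differential(spec$differential)
  } else {
    counts <- as.matrix(utils::read.delim(spec$counts, row.names = 1L,
                                          check.names = FALSE))
    samples <- utils::read.delim(spec$samples, stringsAsFactors = FALSE)
    counts <- counts[, samples$sample_id, drop = FALSE]
    keep <- filter_median_count(counts)
    d <- simple_de_test(counts[keep, , drop = FALSE], samples$genotype,
                        reference = "wildtype")
    d$qvalue <- compute_qvalues(d$pvalue)
    d
  }
  peaks <- if (!is.null(spec$peaks)) read_bed(spec$peaks) else NULL
  list(diff = diff, peaks = peaks)
}

#' Run the full cross-cell-type comparison pipeline
#'
#' Executes the requested stages in dependency order — load/compute
#' differential tables, build peak matchings, then overlap, concordance,
#' peak-set, decile and stepwise analyses — writing every stage's table
#' under `out_dir` together with a manifest (package version, seed, config
#' hash). Identical config and seed reproduce identical outputs; all
#' randomness flows from the master seed through named substreams, so
#' toggling one stage never changes another stage's draws.
#'
#' @param config run configuration; see [validate_run_config()].
#' @return invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[atacshare] ", ...)

  cts <- names(config$cell_types)
  data <- list()
  for (ct in cts) {
    t0 <- Sys.time()
    data[[ct]] <- with_seed(substream_seed(config$seed, paste0("load_", ct)),
                            load_cell_type(config$cell_types[[ct]]))
    write_differential(data[[ct]]$diff,
                       file.path(config$out_dir,
                                 paste0(ct, "_differential.tsv")))
    log_stage("differential[", ct, "] done in ",
              format(Sys.time() - t0, digits = 2))
  }
  ann <- lapply(config$annotations, function(p)
    if (!is.null(p)) read_bed(p) else NULL)

  restrict_shared <- function(a, b) {
    mm <- match_peaks(data[[a]]$peaks, data[[b]]$peaks)
    mm[lengths(mm) > 0L]
  }
  results <- list()
  pair <- cts[1:2]
  if (any(c("overlap", "concordance", "stepwise") %in% config$analyses)) {
    if (is.null(data[[pair[1]]]$peaks) || is.null(data[[pair[2]]]$peaks))
      stop("stage overlap: peak BEDs required for matching")
    m12 <- restrict_shared(pair[1], pair[2])
  }
  if ("overlap" %in% config$analyses) {
    t0 <- Sys.time()
    results$overlap <- conditional_overlap(
      data[[pair[1]]]$diff, data[[pair[2]]]$diff, m12,
      threshold_q = config$q_threshold, n_perm = config$n_perm_overlap,
      seed = substream_seed(config$seed, "overlap"))
    utils::write.table(overlap_report(results$overlap),
                       file.path(config$out_dir, "overlap_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("overlap done in ", format(Sys.time() - t0, digits = 2))
  }
  if ("concordance" %in% config$analyses) {
    t0 <- Sys.time()
    results$concordance <- sign_concordance(
      data[[pair[1]]]$diff, data[[pair[2]]]$diff, m12,
      threshold_q = config$q_threshold, n_perm = config$n_perm_concordance,
      seed = substream_seed(config$seed, "concordance"))
    utils::write.table(overlap_report(results$concordance),
                       file.path(config$out_dir, "concordance_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("concordance done in ", format(Sys.time() - t0, digits = 2))
  }
  if ("peakset" %in% config$analyses && !is.null(ann$clock_cpg)) {
    t0 <- Sys.time()
    results$peakset <- lapply(cts, function(ct) {
      flags <- annotate(data[[ct]]$peaks, ann$clock_cpg)
      ids <- data[[ct]]$peaks$id[flags]
      ids <- intersect(ids, data[[ct]]$diff$peak_id)
      if (length(ids) < 2L) return(NULL)
      peakset_ranksum_test(data[[ct]]$diff, ids,
                           n_perm = config$n_perm_peakset,
                           seed = substream_seed(config$seed,
                                                 paste0("peakset_", ct)))
    })
    names(results$peakset) <- cts
    ok <- !vapply(results$peakset, is.null, TRUE)
    if (any(ok)) {
      tab <- do.call(rbind, lapply(cts[ok], function(ct) {
        r <- results$peakset[[ct]]
        data.frame(cell_type = ct, W_observed = r$W_observed,
                   null_mean_W = mean(r$null_W), set_size = r$set_size,
                   empirical_p_low = r$empirical_p_low)
      }))
      utils::write.table(tab, file.path(config$out_dir, "peakset_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log_stage("peakset done in ", format(Sys.time() - t0, digits = 2))
  }
  if ("decile" %in% config$analyses && !is.null(ann$cpg_island)) {
    t0 <- Sys.time()
    results$decile <- lapply(cts, function(ct) {
      pk <- data[[ct]]$peaks
      pk <- pk[match(data[[ct]]$diff$peak_id, pk$id), , drop = FALSE]
      decile_profile(data[[ct]]$diff, annotate(pk, ann$cpg_island))
    })
    names(results$decile) <- cts
    tab <- do.call(rbind, lapply(cts, function(ct)
      cbind(cell_type = ct, results$decile[[ct]]$profile,
            deviance_ratio = results$decile[[ct]]$deviance_ratio)))
    utils::write.table(tab, file.path(config$out_dir, "decile_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("decile done in ", format(Sys.time() - t0, digits = 2))
  }
  if ("stepwise" %in% config$analyses && length(cts) >= 3L) {
    t0 <- Sys.time()
    m23 <- restrict_shared(cts[2], cts[3])
    results$stepwise <- stepwise_select(
      data[[cts[1]]]$diff, data[[cts[2]]]$diff, data[[cts[3]]]$diff,
      m12, m23, q_threshold = config$q_threshold,
      seed = substream_seed(config$seed, "stepwise"))
    for (s in c("step2", "step3")) {
      tab <- results$stepwise[[paste0(s, "_table")]]
      utils::write.table(tab, file.path(config$out_dir,
                                        paste0("stepwise_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    log_stage("stepwise done in ", format(Sys.time() - t0, digits = 2))
  }

  manifest <- list(
    package = "atacshare",
    version = as.character(utils::packageVersion("atacshare")),
    seed = config$seed,
    q_threshold = config$q_threshold,
    analyses = config$analyses,
    cell_types = cts,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
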