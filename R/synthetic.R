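#' Configuration for the synthetic multi-cell-type ATAC experiment
#'
#' Defines the study conditions the generator emulates: several cell types
#' sharing part of their peak universe, a planted disrupted subset per cell
#' type with controllable cross-cell-type sharing and sign concordance,
#' negative-binomial counts with a higher baseline at CpG-island peaks, and
#' promoter / CpG-island / clock-CpG annotation tracks.
#'
#' Defaults mirror the structure of a sorted-cell ATAC study of a mutant
#' mouse model: ~12% of peaks at promoters, CpG islands at 60% of promoter
#' peaks, 20% of peaks disrupted per cell type, effect sizes mostly under
#' 2-fold (|log2FC| centred at 0.5), NB dispersion 0.1, baseline mean count
#' 151 with a 2.43x CpG-island multiplier, and 5 samples per genotype.
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param n_peaks_shared peaks with identical coordinates/ids in every cell
#'   type.
#' @param n_peaks_specific_per_celltype additional peaks private to each
#'   cell type.
#' @param frac_promoter fraction of peaks overlapping a promoter.
#' @param frac_cpg_island_among_promoters fraction of promoter peaks
#'   overlapping a CpG island.
#' @param frac_clock fraction of peaks containing a clock CpG.
#' @param frac_disrupted fraction of each cell type's universe that is
#'   truly disrupted.
#' @param cross_share fraction of cell-type-1 disrupted shared peaks forced
#'   to be disrupted in cell type 2 as well; 0 means fully independent
#'   draws, 1 (with equal universes and disruption fractions) makes the
#'   disrupted sets coincide.
#' @param sign_concordance probability that a peak disrupted in both
#'   members of the designated pair gets the same effect sign in both.
#' @param alt_beta_a shape a of the Beta(a, 1) alternative p-value
#'   distribution (fast mode); in (0, 1), smaller = stronger signal.
#' @param lfc_mean,lfc_sd magnitude distribution of true log2 fold changes.
#' @param null_lfc_sd spread of null-peak log2FC noise.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param baseline_mean expected count of a non-CpG peak.
#' @param cpg_mean_multiplier count multiplier at CpG-island peaks.
#' @param n_samples_per_group samples per genotype (counts mode).
#' @param seed master seed; each cell type draws from its own substream.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cell_types = 2L,
                             n_peaks_shared = 10000L,
                             n_peaks_specific_per_celltype = 2000L,
                             frac_promoter = 0.12,
                             frac_cpg_island_among_promoters = 0.6,
                             frac_clock = 0.01,
                             frac_disrupted = 0.2,
                             cross_share = 0.3,
                             sign_concordance = 0.8,
                             alt_beta_a = 0.1,
                             lfc_mean = 0.5,
                             lfc_sd = 0.25,
                             null_lfc_sd = 0.05,
                             nb_dispersion = 0.1,
                             baseline_mean = 151,
                             cpg_mean_multiplier = 2.43,
                             n_samples_per_group = 5L,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("frac_promoter", "frac_cpg_island_among_promoters", "frac_clock",
             "frac_disrupted", "cross_share", "sign_concordance")
  bad <- character()
  for (f in probs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad <- c(bad, f)
  if (cfg$alt_beta_a <= 0 || cfg$alt_beta_a >= 1) bad <- c(bad, "alt_beta_a")
  if (cfg$nb_dispersion <= 0) bad <- c(bad, "nb_dispersion")
  if (cfg$n_cell_types < 2) bad <- c(bad, "n_cell_types")
  if (cfg$n_peaks_shared < 1) bad <- c(bad, "n_peaks_shared")
  if (cfg$n_peaks_specific_per_celltype < 0)
    bad <- c(bad, "n_peaks_specific_per_celltype")
  if (cfg$n_samples_per_group < 2) bad <- c(bad, "n_samples_per_group")
  if (length(bad))
    stop("invalid synthetic_config field(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "synthetic_config"
  cfg
}

ct_names <- function(cfg) paste0("ct", seq_len(cfg$n_cell_types))

#' Generate per-cell-type peak universes with annotation tracks
#'
#' Every cell type gets the same `n_peaks_shared` shared peaks (identical
#' coordinates and ids) plus its own private peaks on a cell-type-specific
#' coordinate block. Peaks are non-overlapping and spaced so a +/- 2 kb
#' promoter window around one peak never touches a neighbour: exactly
#' `frac_promoter` of each universe overlaps a promoter. A CpG-island track
#' covers the configured fraction of promoter peaks, and a clock-CpG track
#' (width-1 intervals) marks a random peak subset.
#'
#' @param config a [synthetic_config()].
#' @return list with `cell_types` (named list of [peak_set()]),
#'   `shared_ids`, `tss` (TSS table), `promoters`, and `tracks`
#'   (`cpg_island`, `clock_cpg` peak sets), plus the config.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  spacing <- 6000L; width <- 500L
  build_block <- function(n, chrom, prefix) {
    start <- (seq_len(n) - 1L) * spacing + 1000L
    peak_set(rep(chrom, n), start, start + width,
             paste0(prefix, seq_len(n) - 1L))
  }
  shared <- build_block(config$n_peaks_shared, "chrS", "peak_")
  cts <- ct_names(config)
  universes <- list()
  for (k in seq_along(cts)) {
    spec <- if (config$n_peaks_specific_per_celltype > 0)
      build_block(config$n_peaks_specific_per_celltype, paste0("chr", k),
                  paste0(cts[k], "_peak_")) else NULL
    u <- if (is.null(spec)) shared else
      peak_set(c(shared$chrom, spec$chrom), c(shared$start, spec$start),
               c(shared$end, spec$end), c(shared$id, spec$id))
    universes[[cts[k]]] <- u
  }

  all_peaks <- do.call(rbind, lapply(universes, as.data.frame))
  all_peaks <- all_peaks[!duplicated(all_peaks$id), , drop = FALSE]

  seed_u <- substream_seed(config$seed, "universe")
  ann <- with_seed(seed_u, {
    n_all <- nrow(all_peaks)
    n_prom <- round(config$frac_promoter * n_all)
    prom_idx <- if (n_prom > 0) sort(sample.int(n_all, n_prom)) else integer()
    n_cpg <- round(config$frac_cpg_island_among_promoters * n_prom)
    cpg_idx <- if (n_cpg > 0) sort(sample(prom_idx, n_cpg)) else integer()
    n_clock <- round(config$frac_clock * n_all)
    clock_idx <- if (n_clock > 0) sort(sample.int(n_all, n_clock)) else integer()
    list(prom = prom_idx, cpg = cpg_idx, clock = clock_idx)
  })

  tss <- if (length(ann$prom)) data.frame(
    gene_id = paste0("gene_", seq_along(ann$prom)),
    chrom = all_peaks$chrom[ann$prom],
    position = as.integer((all_peaks$start[ann$prom] +
                             all_peaks$end[ann$prom]) %/% 2L),
    strand = rep(c("+", "-"), length.out = length(ann$prom)),
    stringsAsFactors = FALSE)
  else data.frame(gene_id = character(), chrom = character(),
                  position = integer(), strand = character())
  promoters <- if (nrow(tss)) make_promoters(tss, 2000L) else
    peak_set(character(), integer(), integer())

  cpg_track <- if (length(ann$cpg))
    peak_set(all_peaks$chrom[ann$cpg],
             pmax(0L, all_peaks$start[ann$cpg] - 50L),
             all_peaks$end[ann$cpg] + 50L,
             paste0("cpg_", seq_along(ann$cpg))) else
    peak_set(character(), integer(), integer())
  clock_pos <- as.integer((all_peaks$start[ann$clock] +
                             all_peaks$end[ann$clock]) %/% 2L)
  clock_track <- if (length(ann$clock))
    peak_set(all_peaks$chrom[ann$clock], clock_pos, clock_pos + 1L,
             paste0("clock_", seq_along(ann$clock))) else
    peak_set(character(), integer(), integer())

  list(cell_types = universes, shared_ids = shared$id, tss = tss,
       promoters = promoters,
       tracks = list(cpg_island = cpg_track, clock_cpg = clock_track),
       config = config)
}

#' Plant ground-truth disruption labels and signs
#'
#' Each cell type receives `round(frac_disrupted * universe size)` disrupted
#' peaks. For the designated pair (cell types 1 and 2), a fraction
#' `cross_share` of cell-type-1's disrupted shared peaks is forced into
#' cell type 2's disrupted set; the remainder of cell type 2's quota is
#' drawn uniformly from its universe excluding the forced peaks, so
#' `cross_share = 0` gives fully independent draws. Signs are +/-1 with
#' probability 1/2; peaks disrupted in both members of the pair share their
#' sign with probability `sign_concordance`. True |log2FC| values are
#' |Normal(lfc_mean, lfc_sd)|.
#'
#' @param universe result of [generate_universe()].
#' @param config the same [synthetic_config()].
#' @return list of class `synthetic_truth`: per cell type a data.frame
#'   (`peak_id`, `sign`, `lfc`) of disrupted peaks.
#' @export
assign_truth <- function(universe, config) {
  cts <- names(universe$cell_types)
  truth <- list()
  draw_tab <- function(ids) {
    sgn <- sample(c(-1, 1), length(ids), replace = TRUE)
    data.frame(peak_id = ids, sign = sgn,
               lfc = sgn * abs(stats::rnorm(length(ids), config$lfc_mean,
                                            config$lfc_sd)),
               stringsAsFactors = FALSE)
  }
  for (k in seq_along(cts)) {
    u <- universe$cell_types[[cts[k]]]
    n_dis <- round(config$frac_disrupted * nrow(u))
    sk <- substream_seed(config$seed, paste0("truth_", cts[k]))
    truth[[cts[k]]] <- with_seed(sk, {
      if (k == 2L) {
        t1 <- truth[[cts[1]]]
        s1_shared <- intersect(t1$peak_id, universe$shared_ids)
        s1_shared <- intersect(s1_shared, u$id)
        n_forced <- round(config$cross_share * length(s1_shared))
        if (n_forced > n_dis)
          stop("cross_share demands more shared disrupted peaks (", n_forced,
               ") than cell type 2's disruption quota (", n_dis, ")")
        forced <- if (n_forced > 0)
          sample(s1_shared, n_forced) else character()
        pool <- setdiff(u$id, forced)
        rest <- sample(pool, n_dis - length(forced))
        ids <- c(forced, rest)
        tab <- draw_tab(ids)
        both <- intersect(ids, t1$peak_id)
        if (length(both)) {
          same <- stats::runif(length(both)) < config$sign_concordance
          s1 <- stats::setNames(t1$sign, t1$peak_id)[both]
          new_sign <- ifelse(same, s1, -s1)
          i <- match(both, tab$peak_id)
          flip <- new_sign != tab$sign[i]
          tab$sign[i] <- new_sign
          tab$lfc[i] <- ifelse(flip, -tab$lfc[i], tab$lfc[i])
        }
        tab
      } else {
        draw_tab(sample(u$id, n_dis))
      }
    })
  }
  structure(truth, class = "synthetic_truth")
}

#' Generate per-cell-type differential tables (fast mode)
#'
#' Draws summary statistics directly: null peaks get p ~ Uniform(0,1) and
#' log2FC ~ Normal(0, null_lfc_sd); disrupted peaks get p ~ Beta(a, 1)
#' (dense near 0 for a < 1) and log2FC = planted sign x |magnitude|.
#' Base means follow a log-normal around `baseline_mean`, multiplied by
#' `cpg_mean_multiplier` at CpG-island peaks.
#'
#' @param universe result of [generate_universe()].
#' @param truth result of [assign_truth()].
#' @param config the same [synthetic_config()].
#' @return named list of differential tables (one per cell type) with
#'   `peak_id`, `log2FC`, `pvalue`, `baseMean`.
#' @export
generate_stats <- function(universe, truth, config) {
  out <- list()
  for (ct in names(universe$cell_types)) {
    u <- universe$cell_types[[ct]]
    sk <- substream_seed(config$seed, paste0("stats_", ct))
    out[[ct]] <- with_seed(sk, {
      m <- nrow(u)
      t_ct <- truth[[ct]]
      dis <- u$id %in% t_ct$peak_id
      p <- stats::runif(m)
      p[dis] <- stats::rbeta(sum(dis), config$alt_beta_a, 1)
      lfc <- stats::rnorm(m, 0, config$null_lfc_sd)
      lfc[dis] <- stats::setNames(t_ct$lfc, t_ct$peak_id)[u$id[dis]]
      is_cpg <- annotate(u, universe$tracks$cpg_island)
      mu <- config$baseline_mean * config$cpg_mean_multiplier^is_cpg
      data.frame(peak_id = u$id, log2FC = lfc, pvalue = p,
                 baseMean = mu * exp(stats::rnorm(m, 0, 0.3)),
                 stringsAsFactors = FALSE)
    })
  }
  out
}

#' Generate per-cell-type count matrices (counts mode)
#'
#' Counts are negative binomial with dispersion `nb_dispersion`. A peak's
#' expected count is `baseline_mean`, times `cpg_mean_multiplier` if it
#' overlaps a CpG island, times `2^lfc` in mutant samples of peaks planted
#' as disrupted in that cell type.
#'
#' @inheritParams generate_stats
#' @return named list per cell type: `counts` (peak x sample integer
#'   matrix) and `groups` (sample labels, `wildtype` / `mutant`).
#' @export
generate_counts <- function(universe, truth, config) {
  n <- config$n_samples_per_group
  out <- list()
  for (ct in names(universe$cell_types)) {
    u <- universe$cell_types[[ct]]
    sk <- substream_seed(config$seed, paste0("counts_", ct))
    out[[ct]] <- with_seed(sk, {
      m <- nrow(u)
      t_ct <- truth[[ct]]
      lfc <- stats::setNames(rep(0, m), u$id)
      lfc[t_ct$peak_id] <- t_ct$lfc
      is_cpg <- annotate(u, universe$tracks$cpg_island)
      mu0 <- config$baseline_mean * config$cpg_mean_multiplier^is_cpg
      groups <- rep(c("wildtype", "mutant"), each = n)
      mu <- outer(mu0, rep(1, 2 * n)) *
        2^outer(lfc, as.numeric(groups == "mutant"))
      counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                      size = 1 / config$nb_dispersion),
                       nrow = m,
                       dimnames = list(u$id, paste0(ct, "_", groups, "_",
                                                    seq_len(2 * n))))
      list(counts = counts, groups = groups)
    })
  }
  out
}

#' Write a synthetic experiment to disk
#'
#' Thin wrapper over the generators: writes per-cell-type peak BEDs and
#' differential tables (fast mode) or count TSVs plus a sample sheet
#' (counts mode), the annotation BEDs, the TSS table, and the ground-truth
#' labels. Byte-identical output for identical config.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @param mode `"stats"` (default) or `"counts"`.
#' @return invisibly, the list of generated objects.
#' @export
simulate_experiment <- function(config, out_dir, mode = c("stats", "counts")) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  uni <- generate_universe(config)
  truth <- assign_truth(uni, config)
  for (ct in names(uni$cell_types))
    write_bed(uni$cell_types[[ct]], file.path(out_dir, paste0(ct, "_peaks.bed")))
  write_bed(uni$tracks$cpg_island, file.path(out_dir, "cpg_islands.bed"))
  write_bed(uni$tracks$clock_cpg, file.path(out_dir, "clock_cpgs.bed"))
  utils::write.table(uni$tss, file.path(out_dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (ct in names(truth))
    utils::write.table(truth[[ct]], file.path(out_dir, paste0(ct, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  data_out <- if (mode == "stats") {
    tabs <- generate_stats(uni, truth, config)
    for (ct in names(tabs))
      write_differential(tabs[[ct]],
                         file.path(out_dir, paste0(ct, "_differential.tsv")))
    tabs
  } else {
    cms <- generate_counts(uni, truth, config)
    for (ct in names(cms)) {
      utils::write.table(cms[[ct]]$counts,
                         file.path(out_dir, paste0(ct, "_counts.tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(
        data.frame(sample_id = colnames(cms[[ct]]$counts),
                   genotype = cms[[ct]]$groups),
        file.path(out_dir, paste0(ct, "_samples.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cms
  }
  invisible(list(universe = uni, truth = truth, data = data_out))
}
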