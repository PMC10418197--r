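#' Construct a peak set
#'
#' A peak set is a plain data frame describing genomic intervals in 0-based
#' half-open (BED) coordinates, with columns `chrom`, `start`, `end`, `id`
#' and optionally `score`. It is the unit all analyses in this package
#' operate on: per-cell-type peak universes, promoter windows, and
#' annotation tracks (CpG islands, blacklists, clock-CpG positions) are all
#' peak sets.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open interval bounds,
#'   `start < end` elementwise.
#' @param id unique peak identifiers; generated as `peak_{i}` (0-based, in
#'   input order) when `NULL`.
#' @param score optional non-negative numeric score.
#' @param genome_label free-text genome tag stored as an attribute.
#' @return data.frame of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, id = NULL, score = NULL,
                     genome_label = "synthetic") {
  n <- length(chrom)
  if (is.null(id))
    id <- if (n) paste0("peak_", seq_len(n) - 1L) else character()
  ps <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   id = as.character(id),
                   stringsAsFactors = FALSE)
  if (!is.null(score)) ps$score <- as.numeric(score)
  validate_peak_set(ps)
  attr(ps, "genome_label") <- genome_label
  class(ps) <- c("peak_set", "data.frame")
  ps
}

validate_peak_set <- function(ps) {
  if (nrow(ps) == 0L) return(invisible(ps))
  if (any(!nzchar(ps$chrom)) || anyNA(ps$chrom))
    stop("peak set has empty chromosome names")
  if (anyNA(ps$start) || anyNA(ps$end))
    stop("peak set has non-integer coordinates")
  bad <- which(ps$start >= ps$end)
  if (length(bad))
    stop("peak set has start >= end at row(s) ", paste(bad, collapse = ", "))
  if (anyDuplicated(ps$id))
    stop("duplicate peak ids: ",
         paste(unique(ps$id[duplicated(ps$id)]), collapse = ", "))
  invisible(ps)
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set with", nrow(x), "peaks on",
      length(unique(x$chrom)), "chromosome(s)\n")
  NextMethod()
}

as_granges <- function(ps) {
  GenomicRanges::GRanges(
    seqnames = ps$chrom,
    ranges = IRanges::IRanges(start = ps$start + 1L, end = ps$end),
    id = ps$id)
}

#' Read a BED or narrowPeak file as a peak set
#'
#' Accepts BED3, BED6 and 10-column narrowPeak. Coordinates are kept as
#' stored (0-based half-open). Ids come from column 4 when present and
#' non-"." and are otherwise generated as `peak_{i}` in file order.
#'
#' @param path path to a tab-separated BED-like file.
#' @param format one of `"auto"`, `"bed3"`, `"bed6"`, `"narrowPeak"`;
#'   `"auto"` infers from the column count.
#' @return a [peak_set()].
#' @export
read_bed <- function(path, format = c("auto", "bed3", "bed6", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(peak_set(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- switch(format, auto = 3L, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  bad <- which(nf < need)
  if (length(bad))
    stop("line ", bad[1], ": expected >= ", need, " tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start_c <- vapply(fields, `[[`, "", 2L)
  end_c <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.integer(start_c))
  end <- suppressWarnings(as.integer(end_c))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", bad[1], ": non-integer coordinates ('",
         start_c[bad[1]], "', '", end_c[bad[1]], "')")
  bad <- which(start >= end)
  if (length(bad))
    stop("line ", bad[1], ": start >= end (", start[bad[1]], " >= ",
         end[bad[1]], ")")
  id <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else rep(".", length(nf))
  if (any(id == ".") || anyDuplicated(id))
    id <- paste0("peak_", seq_along(id) - 1L)
  score <- if (all(nf >= 5L))
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))) else NULL
  peak_set(chrom, start, end, id, score, genome_label = basename(path))
}

#' Write a peak set as BED
#'
#' Emits BED4 (or BED5 when a score column is present), preserving the
#' 0-based half-open coordinates.
#'
#' @param ps a [peak_set()].
#' @param path output path.
#' @export
write_bed <- function(ps, path) {
  cols <- c("chrom", "start", "end", "id")
  if (!is.null(ps$score)) cols <- c(cols, "score")
  utils::write.table(as.data.frame(ps)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated with header `gene_id, chrom, position, strand`; positions
#' 0-based, strand `+` or `-`.
#'
#' @param path file path.
#' @return data.frame with those four columns.
#' @export
read_tss <- function(path) {
  tss <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "position", "strand")
  miss <- setdiff(req, names(tss))
  if (length(miss)) stop("TSS table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(tss$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'")
  tss
}

#' Test overlap of two intervals
#'
#' Two peaks overlap when they share a chromosome and the intersection of
#' their half-open intervals spans at least `min_overlap` base pairs. The
#' default of one shared base pair is the overlap convention used
#' throughout the package.
#'
#' @param a,b single-row peak sets or lists with `chrom`, `start`, `end`.
#' @param min_overlap minimum intersection width in bp (>= 1).
#' @return logical scalar.
#' @export
overlaps <- function(a, b, min_overlap = 1L) {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  inter <- min(a$end[1], b$end[1]) - max(a$start[1], b$start[1])
  inter >= min_overlap
}

#' Map each query peak to the subject peaks it overlaps
#'
#' Overlap requires at least `min_overlap` shared base pairs (default 1).
#' The result is deterministic regardless of input order: queries are
#' reported in query order and subject ids within each element are sorted.
#'
#' @param query,subject [peak_set()]s.
#' @param min_overlap minimum intersection width in bp.
#' @return named list, one (possibly empty) character vector of subject ids
#'   per query id.
#' @export
match_peaks <- function(query, subject, min_overlap = 1L) {
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject),
                                minoverlap = min_overlap))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out <- split(subject$id[sh], factor(query$id[qh], levels = query$id))
  lapply(out, function(v) sort(unique(v)))
}

#' Build promoter windows around transcription start sites
#'
#' A promoter is the symmetric window `[position - flank, position + flank)`
#' around a TSS, clipped at zero. The same window is used for both strands
#' (a symmetric flank makes strand irrelevant to the interval). Genes with
#' several annotated TSSs contribute several windows; ids are
#' `gene_id` for a gene's first window and `gene_id@k` for subsequent ones.
#'
#' @param tss data.frame with `gene_id`, `chrom`, `position`, `strand`.
#' @param flank half-width in bp (default 2000, i.e. +/- 2 kb).
#' @return a [peak_set()] whose ids carry the gene id; the `gene_id` column
#'   holds it explicitly.
#' @export
make_promoters <- function(tss, flank = 2000L) {
  if (flank <= 0L) stop("flank must be positive")
  start <- pmax(0L, as.integer(tss$position) - as.integer(flank))
  end <- as.integer(tss$position) + as.integer(flank)
  id <- stats::ave(tss$gene_id, tss$gene_id, FUN = function(g)
    if (length(g) == 1L) g else paste0(g, "@", seq_along(g)))
  ps <- peak_set(tss$chrom, start, end, id)
  ps$gene_id <- tss$gene_id
  ps
}

#' Flag peaks overlapping an annotation track
#'
#' @param peaks a [peak_set()].
#' @param track a [peak_set()]-like annotation (CpG islands, clock-CpG
#'   positions as width-1 intervals, ...).
#' @param min_overlap minimum shared base pairs (default 1).
#' @return logical vector aligned with `peaks` rows; peaks on chromosomes
#'   absent from the track are `FALSE`.
#' @export
annotate <- function(peaks, track, min_overlap = 1L) {
  if (nrow(track) == 0L) return(rep(FALSE, nrow(peaks)))
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(peaks), as_granges(track),
                                 minoverlap = min_overlap)) > 0L
}

#' Drop peaks overlapping a blacklist
#'
#' Removes every peak with a >= 1 bp overlap with any blacklist interval;
#' the surviving peaks keep their input order. Applying the same blacklist
#' twice is a no-op.
#'
#' @param peaks a [peak_set()].
#' @param blacklist annotation peak set of regions to exclude.
#' @return filtered [peak_set()].
#' @export
exclude_blacklist <- function(peaks, blacklist) {
  keep <- !annotate(peaks, blacklist)
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}
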