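#' Seed-anchored candidate windows on transcripts
#'
#' Converts seed matches (transcript coordinates) into candidate CLIP peak
#' windows extending `flank` nucleotides either side of the match, clipped
#' at transcript bounds.  Overlapping or adjacent windows of the same seed
#' type are merged; windows of different seed types are kept separate even
#' when they overlap.
#'
#' @param matches `data.frame` from [scan_utr()] (gene_id, word,
#'   seed_name, start); `seed_name` is mapped to a seed type via
#'   `seed_types`.
#' @param transcript_lengths Named integer vector of transcript lengths.
#' @param flank Extension either side (default 10).
#' @param seed_types Named character vector mapping seed names to types
#'   (default: names containing "IS" -> `"IS"`, otherwise `"CS"`).
#' @return `GRanges` (seqnames = transcript ids, 0-based half-open
#'   intervals stored as 1-based `GRanges`) with metadata column
#'   `seed_type`.
#' @export
seed_windows <- function(matches, transcript_lengths, flank = 10L,
                         seed_types = NULL) {
  flank <- as.integer(flank)
  if (!nrow(matches))
    return(GenomicRanges::GRanges(seed_type = character()))
  if (is.null(seed_types)) {
    type <- ifelse(grepl("IS", matches$seed_name), "IS", "CS")
  } else type <- unname(seed_types[matches$seed_name])
  if (anyNA(type)) stop("seed_name values without a seed type mapping")
  tl <- transcript_lengths[matches$gene_id]
  if (anyNA(tl)) stop("matches on transcripts without a length entry")
  k <- nchar(matches$word)
  start1 <- pmax(1L, matches$start + 1L - flank)        # 1-based
  end1 <- pmin(as.integer(tl), matches$start + k + flank)
  gr <- GenomicRanges::GRanges(matches$gene_id,
                               IRanges::IRanges(start1, end1),
                               strand = "+")
  out <- lapply(unique(type), function(tp) {
    red <- GenomicRanges::reduce(gr[type == tp])
    S4Vectors::mcols(red)$seed_type <- tp
    red
  })
  res <- sort(do.call(c, out))
  res
}

#' Count reads overlapping candidate windows
#'
#' A read contributes its collapsed-duplicate count (the `count` metadata
#' column, default 1) to every window it overlaps by at least one base.
#'
#' @param windows `GRanges` of candidate windows.
#' @param reads `GRanges` of aligned reads (optional `count` column).
#' @return Integer vector of counts, one per window.
#' @export
count_overlaps <- function(windows, reads) {
  cnt <- S4Vectors::mcols(reads)$count
  if (is.null(cnt)) cnt <- rep(1L, length(reads))
  lv <- union(GenomeInfoDb::seqlevels(windows),
              GenomeInfoDb::seqlevels(reads))
  GenomeInfoDb::seqlevels(windows) <- lv
  GenomeInfoDb::seqlevels(reads) <- lv
  hits <- GenomicRanges::findOverlaps(windows, reads, minoverlap = 1L,
                                      ignore.strand = TRUE)
  out <- rep(0L, length(windows))
  if (length(hits)) {
    s <- tapply(cnt[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), sum)
    out[as.integer(names(s))] <- as.integer(s)
  }
  out
}

#' Call seed-anchored peaks against a matched control library
#'
#' A window is a positive peak when its treatment read count reaches
#' `min_treat` and its library-size-normalised, pseudocounted enrichment
#' over the control reaches `min_fold`:
#' `((n_treat + pc) / libsize_treat) / ((n_ctrl + pc) / libsize_ctrl)`.
#' With `test = "poisson"` the fold criterion is replaced by a one-sided
#' Poisson test of the treatment count against the scaled control rate at
#' level `alpha`.
#'
#' @param windows `GRanges` from [seed_windows()].
#' @param treat_reads,ctrl_reads `GRanges` of reads.
#' @param libsize_treat,libsize_ctrl Library sizes (default: total read
#'   counts of each input).
#' @param min_treat Minimum raw treatment count (default 5).
#' @param min_fold Minimum normalised enrichment (default 2).
#' @param pseudocount Added to both counts (default 1).
#' @param test `"fold"` (default) or `"poisson"`.
#' @param alpha Significance level for the Poisson test.
#' @return `data.frame` with one row per window: `gene_id`, `start`,
#'   `end` (0-based half-open), `seed_type`, `n_treat`, `n_ctrl`,
#'   `enrichment`, `positive` (and `p` for the Poisson test).
#' @export
call_peaks <- function(windows, treat_reads, ctrl_reads,
                       libsize_treat = NULL, libsize_ctrl = NULL,
                       min_treat = 5L, min_fold = 2.0, pseudocount = 1.0,
                       test = c("fold", "poisson"), alpha = 0.01) {
  test <- match.arg(test)
  lib_of <- function(reads) {
    cnt <- S4Vectors::mcols(reads)$count
    if (is.null(cnt)) length(reads) else sum(cnt)
  }
  libsize_treat <- libsize_treat %||% lib_of(treat_reads)
  libsize_ctrl <- libsize_ctrl %||% lib_of(ctrl_reads)
  if (libsize_treat <= 0 || libsize_ctrl <= 0)
    stop("library sizes must be positive")
  n_treat <- count_overlaps(windows, treat_reads)
  n_ctrl <- count_overlaps(windows, ctrl_reads)
  enrichment <- ((n_treat + pseudocount) / libsize_treat) /
    ((n_ctrl + pseudocount) / libsize_ctrl)
  out <- data.frame(
    gene_id = as.character(GenomicRanges::seqnames(windows)),
    start = GenomicRanges::start(windows) - 1L,
    end = GenomicRanges::end(windows),
    seed_type = S4Vectors::mcols(windows)$seed_type %||%
      rep(NA_character_, length(windows)),
    n_treat = n_treat, n_ctrl = n_ctrl, enrichment = enrichment,
    stringsAsFactors = FALSE)
  if (test == "fold") {
    out$positive <- n_treat >= min_treat & enrichment >= min_fold
  } else {
    lambda <- (n_ctrl + pseudocount) * libsize_treat / libsize_ctrl
    out$p <- ppois(n_treat - 1L, lambda, lower.tail = FALSE)
    out$positive <- n_treat >= min_treat & out$p < alpha
  }
  out
}

#' Annotate a peak with its transcript region
#'
#' Assigns `UTR5`, `CDS` or `UTR3` by the peak midpoint; with half-open
#' spans the midpoint falls into exactly one region.  Midpoint of
#' `[start, end)` is `floor((start + end) / 2)`, so a midpoint sitting on
#' a junction belongs to the downstream span.
#'
#' @param peaks `data.frame` from [call_peaks()].
#' @param transcript_model `data.frame` with columns `gene_id`, `region`
#'   (`UTR5`/`CDS`/`UTR3`), `start`, `end` (0-based half-open spans).
#' @return `peaks` with a `region` column added.
#' @export
annotate_region <- function(peaks, transcript_model) {
  stopifnot(all(c("gene_id", "region", "start", "end") %in%
                names(transcript_model)))
  mid <- (peaks$start + peaks$end) %/% 2L
  region <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    tm <- transcript_model[transcript_model$gene_id == peaks$gene_id[i], ]
    hit <- tm$region[mid[i] >= tm$start & mid[i] < tm$end]
    if (length(hit) != 1L)
      stop("peak midpoint ", mid[i], " on ", peaks$gene_id[i],
           " falls outside the transcript model")
    region[i] <- hit
  }
  peaks$region <- region
  peaks
}

#' Overlap of positive 3'UTR peaks with down-regulated genes
#'
#' For each seed type, among genes carrying a positive peak annotated to
#' the 3'UTR, the fraction that are also in the down-regulated set.
#'
#' @param peaks Annotated peaks (with `region`, `positive`).
#' @param down_gene_set Character vector of down-regulated gene ids.
#' @return `data.frame` with `seed_type`, `n_genes` (denominator),
#'   `n_down`, `fraction` (`NA` when the denominator is empty).
#' @export
overlap_with_expression <- function(peaks, down_gene_set) {
  pk <- peaks[peaks$positive & peaks$region == "UTR3", , drop = FALSE]
  types <- unique(peaks$seed_type)
  rows <- lapply(types, function(tp) {
    genes <- unique(pk$gene_id[pk$seed_type == tp])
    n <- length(genes)
    nd <- sum(genes %in% down_gene_set)
    if (n == 0L)
      warning("no positive UTR3 peaks for seed type ", tp,
              "; fraction undefined")
    data.frame(seed_type = tp, n_genes = n, n_down = nd,
               fraction = if (n) nd / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a BED6 file of aligned reads into GRanges
#'
#' The BED score column is interpreted as the collapsed-duplicate read
#' count (stored as `count`; scores of 0/NA become 1).
#'
#' @param path BED6 file.
#' @return `GRanges` with a `count` metadata column.
#' @export
read_bed_reads <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  cnt <- S4Vectors::mcols(gr)$score
  if (is.null(cnt)) cnt <- rep(1L, length(gr))
  cnt[is.na(cnt) | cnt < 1L] <- 1L
  S4Vectors::mcols(gr)$count <- as.integer(cnt)
  gr
}

#' Write peaks as BED6+ with peak statistics
#' @param peaks Peak `data.frame` (from [call_peaks()], optionally
#'   annotated).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(chrom = peaks$gene_id, chromStart = peaks$start,
                   chromEnd = peaks$end,
                   name = paste0(peaks$seed_type, "_peak_",
                                 seq_len(nrow(peaks))),
                   score = round(peaks$enrichment, 3), strand = "+",
                   n_treat = peaks$n_treat, n_ctrl = peaks$n_ctrl,
                   positive = peaks$positive,
                   region = peaks$region %||% rep(".", nrow(peaks)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
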