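#' 5'-end isomiR offset profile of a miRNA locus
#'
#' Measures, for every read overlapping the mature locus on its strand,
#' the offset of the read 5' end from the canonical mature 5' end in
#' mature orientation (positive = truncated, negative = extended).
#' Offsets beyond `max_offset` in either direction are pooled into an
#' `"other"` bin.  Fractions are reported both of locus reads and of total
#' genome-mapped reads.
#'
#' @param reads `GRanges` of small-RNA alignments (optional `count`
#'   column for collapsed duplicates).
#' @param mature_interval `GRanges` of length 1: the canonical mature
#'   locus (its strand defines mature orientation).
#' @param max_offset Largest offset kept as its own bin (default 5).
#' @param total_mapped Total genome-mapped read count used for the
#'   normalised fraction (default: total count of `reads`).
#' @return Object of class `isomir_profile`: `data.frame` with columns
#'   `offset` (character: integer offsets and possibly `"other"`),
#'   `count`, `frac_locus`, `frac_total`, plus attributes `mirna`
#'   (seqname) and `n_locus`.  Zero locus reads give a zero-row profile
#'   with a warning.
#' @export
five_prime_offsets <- function(reads, mature_interval, max_offset = 5L,
                               total_mapped = NULL) {
  stopifnot(is(reads, "GRanges"), is(mature_interval, "GRanges"),
            length(mature_interval) == 1L)
  cnt <- S4Vectors::mcols(reads)$count
  if (is.null(cnt)) cnt <- rep(1L, length(reads))
  total_mapped <- total_mapped %||% sum(cnt)
  strand <- as.character(GenomicRanges::strand(mature_interval))
  if (!strand %in% c("+", "-"))
    stop("mature interval must have a definite strand")
  keep <- as.character(GenomicRanges::seqnames(reads)) ==
    as.character(GenomicRanges::seqnames(mature_interval)) &
    as.character(GenomicRanges::strand(reads)) == strand &
    GenomicRanges::start(reads) <= GenomicRanges::end(mature_interval) &
    GenomicRanges::end(reads) >= GenomicRanges::start(mature_interval)
  reads <- reads[keep]; cnt <- cnt[keep]
  mirna_id <- as.character(GenomicRanges::seqnames(mature_interval))
  if (!length(reads)) {
    warning("no reads overlap the mature locus on its strand")
    prof <- data.frame(offset = character(), count = integer(),
                       frac_locus = numeric(), frac_total = numeric())
    attr(prof, "mirna") <- mirna_id
    attr(prof, "n_locus") <- 0L
    class(prof) <- c("isomir_profile", "data.frame")
    return(prof)
  }
  off <- if (strand == "+")
    GenomicRanges::start(reads) - GenomicRanges::start(mature_interval)
  else
    GenomicRanges::end(mature_interval) - GenomicRanges::end(reads)
  lab <- ifelse(abs(off) <= max_offset, as.character(off), "other")
  counts <- tapply(cnt, lab, sum)
  n_locus <- sum(cnt)
  num <- suppressWarnings(as.integer(names(counts)))
  ord <- order(is.na(num), num)
  prof <- data.frame(offset = names(counts)[ord],
                     count = as.integer(counts)[ord],
                     frac_locus = as.numeric(counts)[ord] / n_locus,
                     frac_total = as.numeric(counts)[ord] / total_mapped,
                     stringsAsFactors = FALSE, row.names = NULL)
  attr(prof, "mirna") <- mirna_id
  attr(prof, "n_locus") <- n_locus
  class(prof) <- c("isomir_profile", "data.frame")
  prof
}

#' Seed shifts supported by the isomiR profile
#'
#' Returns the set of 5' truncations (non-negative offsets) whose locus
#' fraction reaches `min_fraction`; these are the shifts for which
#' [shifted_variants()] seed definitions should enter the scan word set.
#' 5'-extended reads (negative offsets) never produce a seed shift, and 3'
#' heterogeneity is ignored throughout.
#'
#' @param profile An [five_prime_offsets()] result.
#' @param min_fraction Minimum locus fraction (default 0.10).
#' @return Sorted integer vector of shifts (possibly empty).
#' @export
active_seed_shifts <- function(profile, min_fraction = 0.10) {
  stopifnot(inherits(profile, "isomir_profile"))
  num <- suppressWarnings(as.integer(profile$offset))
  keep <- !is.na(num) & num >= 0L & profile$frac_locus >= min_fraction
  sort(num[keep])
}

#' Write an isomiR profile to TSV
#' @param profile An [five_prime_offsets()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isomir_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
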