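#' Construct a mature miRNA record
#'
#' A mature miRNA is held as its 5'->3' RNA sequence.  Seed windows
#' ([seed_definition()]) are numbered on this sequence with position 1 at
#' the 5' nucleotide, so the canonical seed occupies positions 2-8 and the
#' internal seed positions 6-12.
#'
#' @param id miRNA identifier.
#' @param sequence RNA sequence 5'->3', alphabet ACGU, length 16-30.
#' @return An object of class `mature_mirna` with elements `id` and
#'   `sequence`.
#' @export
#' @examples
#' mature_mirna("mir-x", "ACGUACGUACGUACGUACGUACGUA")
mature_mirna <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGU]", sequence))
    stop("miRNA '", id, "' contains characters outside ACGU")
  n <- nchar(sequence)
  if (n < 16L || n > 30L)
    stop("miRNA '", id, "' has length ", n, "; expected 16-30 nt")
  structure(list(id = id, sequence = sequence), class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat("mature miRNA ", x$id, " (", nchar(x$sequence), " nt)\n  5'-",
      x$sequence, "-3'\n", sep = "")
  invisible(x)
}

#' Define a seed window on a mature miRNA
#'
#' A seed is a window of `length` nucleotides starting at 1-based position
#' `anchor` on the canonical mature sequence.  `isomir_shift` moves the
#' window toward the 3' end to compensate a 5'-truncated isomiR: a guide
#' shortened by s nucleotides at its 5' end presents the window
#' `anchor+s ... anchor+s+length-1` of the canonical sequence at the same
#' distance from its own 5' end.
#'
#' @param name Label, e.g. `"CS"`, `"IS"`, `"CS+1"`.
#' @param anchor 1-based first seed position on the canonical miRNA
#'   (canonical seed: 2; internal seed: 6).
#' @param length Word size, 5-9 nt.
#' @param isomir_shift Non-negative 5' truncation compensated by the
#'   definition.
#' @return An object of class `seed_definition`.
#' @seealso [shifted_variants()], [derive_target_word()]
#' @export
#' @examples
#' seed_definition("CS", 2, 7)        # canonical seed, positions 2-8
#' seed_definition("IS", 6, 7)        # internal seed, positions 6-12
seed_definition <- function(name, anchor, length, isomir_shift = 0L) {
  anchor <- as.integer(anchor); length <- as.integer(length)
  isomir_shift <- as.integer(isomir_shift)
  stopifnot(is.character(name), base::length(name) == 1L)
  if (anchor < 1L) stop("seed '", name, "': anchor must be >= 1")
  if (length < 5L || length > 9L)
    stop("seed '", name, "': length must be in [5, 9]")
  if (isomir_shift < 0L) stop("seed '", name, "': isomir_shift must be >= 0")
  structure(list(name = name, anchor = anchor, length = length,
                 isomir_shift = isomir_shift),
            class = "seed_definition")
}

#' @export
print.seed_definition <- function(x, ...) {
  w <- seed_window(x)
  cat("seed ", x$name, ": miRNA positions ", w[1], "-", w[2],
      if (x$isomir_shift > 0) paste0(" (shift +", x$isomir_shift, ")"),
      "\n", sep = "")
  invisible(x)
}

# effective window (start, end) on the canonical mature sequence
seed_window <- function(seed) {
  s <- seed$anchor + seed$isomir_shift
  c(s, s + seed$length - 1L)
}

#' Canonical and internal seed definitions
#'
#' Convenience constructor for the two seed types compared throughout the
#' package: the canonical seed anchored at position 2 and the internal seed
#' anchored at position 6 (7-mers: positions 2-8 and 6-12).
#'
#' @param length Word size (default 7).
#' @return Named list with elements `CS` and `IS`.
#' @export
canonical_seeds <- function(length = 7L) {
  list(CS = seed_definition("CS", 2L, length),
       IS = seed_definition("IS", 6L, length))
}

#' Derive the target word of a seed window
#'
#' The target word is the DNA-alphabet reverse complement of the miRNA
#' subsequence covered by the (shift-adjusted) seed window; it is the exact
#' string whose presence in a 3'UTR constitutes a seed match.
#'
#' @param mirna A [mature_mirna] object.
#' @param seed A [seed_definition] object.
#' @return An object of class `target_word` with elements `word` (DNA
#'   string), `seed` and `source_mirna`.
#' @export
#' @examples
#' derive_target_word(mir4728_3p(), seed_definition("IS", 6, 7))  # GAGGTCA
derive_target_word <- function(mirna, seed) {
  stopifnot(inherits(mirna, "mature_mirna"), inherits(seed, "seed_definition"))
  w <- seed_window(seed)
  n <- nchar(mirna$sequence)
  if (w[2] > n)
    stop("seed '", seed$name, "' window ", w[1], "-", w[2],
         " exceeds miRNA '", mirna$id, "' length ", n)
  win <- substr(mirna$sequence, w[1], w[2])
  word <- chartr("U", "T",
                 as.character(Biostrings::reverseComplement(
                   Biostrings::RNAString(win))))
  structure(list(word = word, seed = seed, source_mirna = mirna$id),
            class = "target_word")
}

#' @export
print.target_word <- function(x, ...) {
  cat("target word ", x$word, " (", x$seed$name, " of ", x$source_mirna,
      ")\n", sep = "")
  invisible(x)
}

#' Shifted seed variants for 5' isomiRs
#'
#' Returns the seed definition together with its `+1 ... +max_shift`
#' variants, each compensating a 5' truncation of that many nucleotides
#' (window moved toward the miRNA 3' end).  Because internal-seed position
#' is set by the distance to the guide 5' end, shifted variants are what a
#' shortened isomiR actually presents.
#'
#' @param seed A [seed_definition].
#' @param max_shift Largest truncation to generate (>= 0).
#' @return List of [seed_definition] objects, shifts `0:max_shift`, named
#'   `name`, `name+1`, ...
#' @export
#' @examples
#' shifted_variants(seed_definition("CS", 2, 7), 1)  # windows 2-8 and 3-9
shifted_variants <- function(seed, max_shift) {
  max_shift <- as.integer(max_shift)
  stopifnot(inherits(seed, "seed_definition"), max_shift >= 0L)
  out <- lapply(0:max_shift, function(s) {
    nm <- if (s == 0L) seed$name else paste0(seed$name, "+", s)
    seed_definition(nm, seed$anchor, seed$length, seed$isomir_shift + s)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Scan a 3'UTR for exact target-word matches
#'
#' Reports every exact, overlapping occurrence of each word on the mRNA
#' sense strand.  Positions are 0-based with half-open intervals
#' `[start, start + nchar(word))`.  `N` in the UTR matches nothing.
#'
#' @param utr Either a single UTR sequence (character) plus `gene_id`, or a
#'   named character vector / `DNAStringSet` of UTRs (names = gene ids).
#' @param words Target words: a character vector, or a list of
#'   `target_word` objects (their seed names are propagated).
#' @param gene_id Gene identifier when `utr` is a single unnamed sequence.
#' @return `data.frame` with columns `gene_id`, `word`, `seed_name`,
#'   `start` (0-based).  Zero rows when nothing matches.
#' @export
#' @examples
#' scan_utr("TTGAGGTCATT", "GAGGTCA", gene_id = "g1")
scan_utr <- function(utr, words, gene_id = NULL) {
  seqs <- as_utr_set(utr, gene_id)
  wtab <- as_word_table(words)
  hits <- vector("list", nrow(wtab))
  for (i in seq_len(nrow(wtab))) {
    w <- wtab$word[i]
    if (any(Biostrings::width(seqs) >= nchar(w))) {
      m <- Biostrings::vmatchPattern(w, seqs, fixed = TRUE)
      st <- Biostrings::startIndex(m)
      n_per <- lengths(st)
      if (sum(n_per) > 0L) {
        hits[[i]] <- data.frame(
          gene_id = rep(names(seqs), n_per),
          word = w,
          seed_name = wtab$seed_name[i],
          start = unlist(st, use.names = FALSE) - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (!length(hits))
    return(data.frame(gene_id = character(), word = character(),
                      seed_name = character(), start = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$gene_id, out$start, out$word), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# normalise UTR input to a named DNAStringSet
as_utr_set <- function(utr, gene_id = NULL) {
  if (is(utr, "DNAStringSet")) {
    seqs <- utr
  } else if (is.character(utr)) {
    utr <- toupper(utr)
    bad <- grepl("[^ACGTN]", utr)
    if (any(bad))
      stop("UTR sequence(s) contain characters outside ACGTN: ",
           paste(head(which(bad)), collapse = ", "))
    seqs <- Biostrings::DNAStringSet(utr)
    if (!is.null(names(utr))) names(seqs) <- names(utr)
  } else stop("unsupported UTR input of class ", class(utr)[1])
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    if (length(seqs) == 1L && !is.null(gene_id)) names(seqs) <- gene_id
    else stop("UTR set must be named by gene_id")
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene_id in UTR set: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

# normalise word input to data.frame(word, seed_name)
as_word_table <- function(words) {
  if (inherits(words, "target_word")) words <- list(words)
  if (is.character(words)) {
    data.frame(word = toupper(words),
               seed_name = if (!is.null(names(words))) names(words)
                           else toupper(words),
               stringsAsFactors = FALSE)
  } else if (is.list(words)) {
    stopifnot(all(vapply(words, inherits, TRUE, "target_word")))
    data.frame(word = vapply(words, `[[`, "", "word"),
               seed_name = vapply(words, function(w) w$seed$name, ""),
               stringsAsFactors = FALSE)
  } else stop("words must be a character vector or list of target_word")
}

#' Classify genes by seed-match content
#'
#' Counts canonical-seed and internal-seed word occurrences per gene
#' (overlapping occurrences all counted, shifted variants aggregated into
#' their seed type) and assigns each gene to one of four mutually exclusive
#' classes: `CS_only`, `IS_only`, `both`, `neither`.  The factor is
#' presence-based: one or more matches of a type counts.
#'
#' @param utrs Named character vector or `DNAStringSet` of 3'UTRs.
#' @param cs_words,is_words Character vectors (or `target_word` lists) of
#'   the canonical-seed and internal-seed word sets; they must be disjoint.
#' @return `data.frame` with columns `gene_id`, `n_cs`, `n_is`, `cls`
#'   (factor with the four levels above), one row per input gene.
#' @export
classify_genes <- function(utrs, cs_words, is_words) {
  seqs <- as_utr_set(utrs)
  cs <- as_word_table(cs_words)$word
  is_ <- as_word_table(is_words)$word
  if (length(intersect(cs, is_)))
    stop("CS and IS word sets overlap: ",
         paste(intersect(cs, is_), collapse = ", "))
  count_set <- function(wset) {
    tot <- integer(length(seqs))
    for (w in wset)
      tot <- tot + Biostrings::vcountPattern(w, seqs, fixed = TRUE)
    tot
  }
  n_cs <- count_set(cs)
  n_is <- count_set(is_)
  cls <- ifelse(n_cs >= 1L & n_is >= 1L, "both",
         ifelse(n_cs >= 1L, "CS_only",
         ifelse(n_is >= 1L, "IS_only", "neither")))
  data.frame(gene_id = names(seqs), n_cs = n_cs, n_is = n_is,
             cls = factor(cls, levels = c("CS_only", "IS_only",
                                          "both", "neither")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract target-site sequence context as a position frequency matrix
#'
#' For every match of `word`, the fragment `flank` bases either side of the
#' site is extracted; positions truncated at a UTR edge are excluded from
#' the affected columns.  Returns per-position nucleotide fractions over
#' all fragments, the logo-style summary used to ask whether anything
#' beyond the seed match itself is conserved.
#'
#' @param utrs Named character vector or `DNAStringSet`.
#' @param word Target word (character scalar or `target_word`).
#' @param flank Bases of context either side (default 10).
#' @return Object of class `position_frequency_matrix`: a list with `pfm`
#'   (4 x (k + 2 flank) matrix of fractions, rows ACGT), `counts`,
#'   `n_fragments`, `word`, `flank`.
#' @export
extract_context <- function(utrs, word, flank = 10L) {
  flank <- as.integer(flank)
  stopifnot(flank >= 0L)
  wtab <- as_word_table(word)
  stopifnot(nrow(wtab) == 1L)
  w <- wtab$word
  k <- nchar(w)
  seqs <- as_utr_set(utrs)
  hits <- scan_utr(seqs, w)
  width <- k + 2L * flank
  counts <- matrix(0L, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  n <- nrow(hits)
  if (n > 0L) {
    seqc <- as.character(seqs)
    for (i in seq_len(n)) {
      s <- seqc[[hits$gene_id[i]]]
      # fragment coordinates, 1-based on the UTR
      from <- hits$start[i] + 1L - flank
      cols <- seq_len(width)
      pos <- from + cols - 1L
      ok <- pos >= 1L & pos <= nchar(s)
      ch <- substring(s, pos[ok], pos[ok])
      idx <- cbind(match(ch, c("A", "C", "G", "T")), cols[ok])
      idx <- idx[!is.na(idx[, 1L]), , drop = FALSE]
      counts[idx] <- counts[idx] + 1L
    }
  }
  tot <- colSums(counts)
  pfm <- sweep(counts, 2L, pmax(tot, 1L), "/")
  structure(list(pfm = pfm, counts = counts, n_fragments = n,
                 word = w, flank = flank),
            class = "position_frequency_matrix")
}

#' @export
print.position_frequency_matrix <- function(x, digits = 3, ...) {
  cat("PFM for word ", x$word, " +/- ", x$flank, " nt over ",
      x$n_fragments, " fragments\n", sep = "")
  print(round(x$pfm, digits))
  invisible(x)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param alphabet `"DNA"` for UTR sets (returns a named character vector,
#'   uppercased) or `"RNA"` for mature miRNAs (returns a list of
#'   [mature_mirna]).
#' @return See `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (alphabet == "DNA") {
    ss <- Biostrings::readDNAStringSet(path)
    setNames(toupper(as.character(ss)), names(ss))
  } else {
    ss <- Biostrings::readRNAStringSet(path)
    mapply(mature_mirna, names(ss), toupper(as.character(ss)),
           SIMPLIFY = FALSE, USE.NAMES = TRUE)
  }
}

#' Write a named sequence set to FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  is_rna <- any(grepl("U", seqs))
  ss <- if (is_rna) Biostrings::RNAStringSet(seqs)
        else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
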