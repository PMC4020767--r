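#' Build a presence-based word index over a UTR set
#'
#' Indexes which genes contain each k-mer at least once (presence, not
#' occurrence counts).  K-mers overlapping an `N` are ignored.  The index
#' is the substrate for the enrichment landscape: for any leading bin of a
#' ranked gene list, the number of bin genes containing a word is a draw
#' from a hypergeometric when the word is unrelated to the ranking.
#'
#' @param utrs Named character vector or `DNAStringSet` of 3'UTRs.
#' @param k Word size, 5-9.
#' @return Object of class `word_index`: list with `k`, `genes`
#'   (character), `presence` (genes x words logical matrix over all
#'   observed words), plus accessors via [genes_with_word()].
#' @export
build_word_index <- function(utrs, k) {
  k <- as.integer(k)
  if (k < 5L || k > 9L) stop("k must be in [5, 9]")
  seqs <- as_utr_set(utrs)
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  presence <- counts > 0L
  rownames(presence) <- names(seqs)
  keep <- colSums(presence) > 0L
  presence <- presence[, keep, drop = FALSE]
  structure(list(k = k, genes = names(seqs), presence = presence),
            class = "word_index")
}

#' @export
print.word_index <- function(x, ...) {
  cat("word index: k = ", x$k, ", ", length(x$genes), " genes, ",
      ncol(x$presence), " distinct words\n", sep = "")
  invisible(x)
}

#' Genes whose UTR contains a word
#' @param index A [build_word_index()] result.
#' @param word k-mer (must match the index k).
#' @return Character vector of gene ids (empty if the word was never seen).
#' @export
genes_with_word <- function(index, word) {
  stopifnot(inherits(index, "word_index"))
  if (nchar(word) != index$k)
    stop("word length ", nchar(word), " != index k ", index$k)
  if (!word %in% colnames(index$presence)) return(character())
  index$genes[index$presence[, word]]
}

#' Exact hypergeometric tail probability
#'
#' One-sided tail of the hypergeometric distribution for `x` marked genes
#' in a sample of `n` from a universe of `N` containing `K` marked genes.
#' `side = "over"` gives P(X >= x), `side = "under"` gives P(X <= x);
#' both are exact (log-space machinery of [stats::phyper()]).  Vectorised
#' over `x`, `K`, `n`.
#'
#' @param x Observed marked count(s).
#' @param K Marked genes in the universe.
#' @param n Sample (leading-bin) size.
#' @param N Universe size.
#' @param side `"over"` or `"under"`.
#' @param log10p Return -log10(p) instead of p.
#' @return Tail probability (or -log10 of it).
#' @export
#' @examples
#' hypergeom_tail(3, K = 3, n = 5, N = 10, side = "over")  # 1/12
hypergeom_tail <- function(x, K, n, N, side = c("over", "under"),
                           log10p = FALSE) {
  side <- match.arg(side)
  m <- max(length(x), length(K), length(n))
  x <- rep_len(x, m); K <- rep_len(K, m); n <- rep_len(n, m)
  if (any(K > N | n > N | x < 0 | x > pmin(K, n)))
    stop("impossible hypergeometric parameters (need 0 <= x <= min(K, n),",
         " K <= N, n <= N)")
  lp <- if (side == "over")
    phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  else
    phyper(x, K, N - K, n, lower.tail = TRUE, log.p = TRUE)
  if (log10p) -lp / log(10) else exp(lp)
}

# leading-bin edges: step, 2*step, ..., always ending exactly at N
landscape_bins <- function(N, step) {
  stopifnot(step >= 1L)
  edges <- seq(from = step, to = N, by = step)
  if (length(edges) == 0L || edges[length(edges)] != N)
    edges <- c(edges, N)
  as.integer(edges)
}

#' Word-enrichment landscape over a ranked gene list
#'
#' For each leading bin of the ranking, the one-sided hypergeometric
#' p-values for over- and under-representation of the word among bin genes
#' are computed; the signed score is `-log10` of the smaller one, positive
#' for over-representation.  The full-list bin is always exactly 0.  A
#' word contained in no UTR gives a flat zero landscape.
#'
#' @param ranked Character vector of gene ids, most down-regulated first
#'   (from [rank_by_downregulation()]); must be a permutation of the
#'   index genes.
#' @param index A [build_word_index()] result.
#' @param word k-mer of the index word size.
#' @param step Leading-bin increment (default `max(1, N %/% 100)`).
#' @return Object of class `enrichment_landscape`: list with `word`,
#'   `bin_edges`, `signed_logp`, `x` (per-bin marked counts), `K`, `N`,
#'   `peak` (list `bin`, `value`).
#' @export
landscape <- function(ranked, index, word, step = NULL) {
  stopifnot(inherits(index, "word_index"))
  if (nchar(word) != index$k)
    stop("word length ", nchar(word), " != index k ", index$k)
  if (length(ranked) != length(index$genes) ||
      !setequal(ranked, index$genes))
    stop("ranked list is not a permutation of the indexed genes")
  N <- length(ranked)
  step <- as.integer(step %||% max(1L, N %/% 100L))
  edges <- landscape_bins(N, step)
  members <- genes_with_word(index, word)
  K <- length(members)
  if (K == 0L) {
    x <- integer(length(edges))
    v <- numeric(length(edges))
  } else {
    ranks <- sort(match(members, ranked))
    x <- findInterval(edges, ranks - 0.5)   # members with rank <= edge
    v <- signed_logp(x, K, edges, N)
  }
  pk <- which.max(v)
  structure(list(word = word, bin_edges = edges, signed_logp = v, x = x,
                 K = K, N = N,
                 peak = list(bin = edges[pk], value = v[pk])),
            class = "enrichment_landscape")
}

# signed -log10 of the smaller one-sided tail; positive = over-represented
signed_logp <- function(x, K, n, N) {
  lo <- hypergeom_tail(x, K, n, N, "over", log10p = TRUE)
  lu <- hypergeom_tail(x, K, n, N, "under", log10p = TRUE)
  ifelse(lo >= lu, lo, -lu)
}

#' @export
print.enrichment_landscape <- function(x, ...) {
  cat("enrichment landscape for ", x$word, " (K = ", x$K, " of N = ",
      x$N, " genes)\n  peak ", format(x$peak$value, digits = 4),
      " at leading bin ", x$peak$bin, "\n", sep = "")
  invisible(x)
}

#' Rank all indexed words by landscape peak
#'
#' Computes the signed landscape for every word in the index and orders
#' words by their maximum signed score (descending), ties broken
#' lexicographically.  Words present in no gene are skipped.
#'
#' @inheritParams landscape
#' @param m Number of words to return (default all).
#' @return `data.frame` with columns `word`, `peak_value`, `peak_bin`, `K`,
#'   ordered by decreasing `peak_value`.
#' @export
top_words <- function(ranked, index, m = Inf, step = NULL) {
  stopifnot(inherits(index, "word_index"))
  if (length(ranked) != length(index$genes) ||
      !setequal(ranked, index$genes))
    stop("ranked list is not a permutation of the indexed genes")
  N <- length(ranked)
  step <- as.integer(step %||% max(1L, N %/% 100L))
  edges <- landscape_bins(N, step)
  pres <- index$presence[match(ranked, rownames(index$presence)), ,
                         drop = FALSE]
  # per-bin cumulative membership counts: bin genes' rowsums, then cumsum
  grp <- findInterval(seq_len(N) - 1L, edges) + 1L  # bin id per rank
  percell <- rowsum(pres + 0L, grp)
  xs <- apply(percell, 2L, cumsum)
  if (is.null(dim(xs))) xs <- matrix(xs, nrow = length(edges))
  K <- xs[nrow(xs), ]
  peak_value <- numeric(ncol(xs)); peak_bin <- integer(ncol(xs))
  for (j in seq_len(ncol(xs))) {
    v <- signed_logp(xs[, j], K[j], edges, N)
    pk <- which.max(v)
    peak_value[j] <- v[pk]; peak_bin[j] <- edges[pk]
  }
  out <- data.frame(word = colnames(pres), peak_value = peak_value,
                    peak_bin = peak_bin, K = as.integer(K),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$peak_value, out$word), , drop = FALSE]
  rownames(out) <- NULL
  head(out, m)
}

#' Write enrichment landscapes to TSV
#' @param landscapes List of `enrichment_landscape` objects.
#' @param path Output TSV (`word`, `bin`, `signed_logp`).
#' @return `path`, invisibly.
#' @export
write_landscapes <- function(landscapes, path) {
  if (inherits(landscapes, "enrichment_landscape"))
    landscapes <- list(landscapes)
  rows <- do.call(rbind, lapply(landscapes, function(l)
    data.frame(word = l$word, bin = l$bin_edges,
               signed_logp = l$signed_logp, stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
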