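#' Plot enrichment landscapes with highlighted seed words
#'
#' Draws signed -log10 hypergeometric scores over the leading bins of the
#' ranked gene list (most down-regulated genes on the left); positive
#' values mean over-representation.  Landscapes for the highlighted seed
#' words are coloured; any others are drawn in grey.
#'
#' @param landscapes List of [landscape()] results.
#' @param highlight Named character vector `word = colour` (default: the
#'   classic CS red / CS+1 green / IS blue / IS+1 purple order applied to
#'   the first four words).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the highlight map.
#' @export
plot_landscapes <- function(landscapes, highlight = NULL, ...) {
  if (inherits(landscapes, "enrichment_landscape"))
    landscapes <- list(landscapes)
  words <- vapply(landscapes, `[[`, "", "word")
  if (is.null(highlight)) {
    cols <- c("red", "forestgreen", "blue", "purple")
    highlight <- setNames(cols[seq_len(min(4L, length(words)))],
                          head(words, 4L))
  }
  ylim <- range(unlist(lapply(landscapes, `[[`, "signed_logp")), 0)
  xlim <- c(0, max(vapply(landscapes, function(l) l$N, 0)))
  plot(NA, xlim = xlim, ylim = ylim,
       xlab = "leading bin size (genes, most down-regulated first)",
       ylab = expression(signed ~ -log[10] ~ p), ...)
  graphics::abline(h = 0, col = "grey70")
  for (l in landscapes) {
    col <- highlight[l$word]
    graphics::lines(l$bin_edges, l$signed_logp,
                    col = if (is.na(col)) "grey80" else col,
                    lwd = if (is.na(col)) 1 else 2)
  }
  hl <- highlight[!is.na(highlight)]
  graphics::legend("topright", legend = names(hl), col = hl, lwd = 2,
                   bty = "n")
  invisible(highlight)
}

#' Plot seed-class ECDF curves
#'
#' The classic four-curve comparison of log2 fold-change distributions for
#' genes with only canonical-seed, only internal-seed, both, or neither
#' site type; repression shifts seed-containing curves to the left.
#'
#' @param dists Output of [build_class_distributions()].
#' @param cols Colours for CS_only / IS_only / both / neither.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `dists`.
#' @export
plot_class_ecdf <- function(dists,
                            cols = c(CS_only = "red", IS_only = "blue",
                                     both = "purple", neither = "grey40"),
                            ...) {
  xs <- range(unlist(lapply(dists, `[[`, "values")))
  plot(NA, xlim = xs, ylim = c(0, 1), xlab = "log2 fold change",
       ylab = "cumulative fraction", ...)
  for (nm in names(dists)) {
    d <- dists[[nm]]
    if (!d$n) next
    graphics::lines(stats::ecdf(d$values), col = cols[nm],
                    do.points = FALSE, verticals = TRUE)
  }
  graphics::legend("topleft",
                   legend = sprintf("%s (n = %d)", names(dists),
                                    vapply(dists, `[[`, 0L, "n")),
                   col = cols[names(dists)], lwd = 2, bty = "n")
  invisible(dists)
}
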