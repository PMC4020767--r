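#' Per-gene differential-expression statistics
#'
#' Computes, for each gene, the mean log2 fold change (treatment minus
#' control), a two-sample Welch t-statistic with Welch-Satterthwaite
#' degrees of freedom, the two-sided p-value, and the Benjamini-Hochberg
#' adjusted p-value.  Input intensities must already be on the log2 scale.
#' Genes with zero variance in both groups and equal means get t = 0,
#' p = 1.
#'
#' @param mat Numeric matrix, genes x samples, log2 intensities; rownames
#'   are gene ids.
#' @param group_labels Character/factor of length `ncol(mat)` with exactly
#'   two distinct values.
#' @param treatment The label naming the treatment group (default
#'   `"treatment"`); the other label is the control.
#' @return `data.frame` with columns `gene_id`, `log2fc`, `t_stat`, `p`,
#'   `p_adj`.
#' @export
per_gene_stats <- function(mat, group_labels, treatment = "treatment") {
  stopifnot(is.matrix(mat), is.numeric(mat),
            length(group_labels) == ncol(mat))
  group_labels <- as.character(group_labels)
  lev <- unique(group_labels)
  if (length(lev) != 2L)
    stop("group_labels must have exactly two distinct values")
  if (!treatment %in% lev)
    stop("treatment label '", treatment, "' not present in group_labels")
  it <- group_labels == treatment
  nt <- sum(it); nc <- sum(!it)
  if (nt < 2L || nc < 2L) stop("need >= 2 samples per group")
  mt <- rowMeans(mat[, it, drop = FALSE])
  mc <- rowMeans(mat[, !it, drop = FALSE])
  vt <- apply(mat[, it, drop = FALSE], 1L, var)
  vc <- apply(mat[, !it, drop = FALSE], 1L, var)
  se2 <- vt / nt + vc / nc
  lfc <- mt - mc
  t_stat <- lfc / sqrt(se2)
  df <- se2^2 / ((vt / nt)^2 / (nt - 1L) + (vc / nc)^2 / (nc - 1L))
  degenerate <- se2 == 0
  t_stat[degenerate & lfc == 0] <- 0
  t_stat[degenerate & lfc != 0] <- sign(lfc[degenerate & lfc != 0]) * Inf
  df[degenerate] <- nt + nc - 2L
  p <- 2 * pt(-abs(t_stat), df)
  p[degenerate & lfc == 0] <- 1
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  data.frame(gene_id = ids, log2fc = lfc, t_stat = t_stat, p = p,
             p_adj = adjust_bh(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(p_values) {
  stopifnot(is.numeric(p_values),
            all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Rank genes from most down- to most up-regulated
#'
#' Orders by ascending t-statistic; ties are broken by lexicographic
#' gene id so the ranking is deterministic.
#'
#' @param records Output of [per_gene_stats()].
#' @return Character vector of gene ids, most down-regulated first.
#' @export
rank_by_downregulation <- function(records) {
  stopifnot(all(c("gene_id", "t_stat") %in% names(records)))
  records$gene_id[order(records$t_stat, records$gene_id)]
}

#' Top down-regulated genes at an FDR cut
#'
#' The first `n` genes of the down-regulation ranking restricted to
#' adjusted p below `alpha`; fewer than `n` may qualify.
#'
#' @param records Output of [per_gene_stats()].
#' @param n Maximum number of genes (default 250).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return Character vector of gene ids.
#' @export
top_down <- function(records, n = 250L, alpha = 0.01) {
  ord <- rank_by_downregulation(records)
  ok <- records$gene_id[records$p_adj < alpha]
  head(ord[ord %in% ok], n)
}

#' Stratify genes into down-regulated and unaffected sets
#'
#' The down set is all genes with t-statistic strictly below `down_cut`.
#' The unaffected set is by default the complement (`t >= down_cut`); the
#' alternative `"t_ge_4"` restricts it to `t >= abs(down_cut)`, i.e. genes
#' at least as far in the opposite tail.
#'
#' @param records Output of [per_gene_stats()].
#' @param down_cut t threshold for down-regulation (default -4).
#' @param unaffected `"complement"` (default) or `"t_ge_4"`.
#' @return List with character vectors `down` and `unaffected`.
#' @export
stratify_by_t <- function(records, down_cut = -4,
                          unaffected = c("complement", "t_ge_4")) {
  unaffected <- match.arg(unaffected)
  down <- records$gene_id[records$t_stat < down_cut]
  un <- switch(unaffected,
               complement = records$gene_id[records$t_stat >= down_cut],
               t_ge_4 = records$gene_id[records$t_stat >= abs(down_cut)])
  list(down = down, unaffected = un)
}

#' Calibrated normalised relative quantities from a Cq table
#'
#' Standard relative qPCR quantification: per-well relative quantity
#' `RQ = efficiency^(meanCq_gene - Cq)`, a per-sample normalisation factor
#' equal to the geometric mean of the reference genes' RQs, `NRQ = RQ/NF`,
#' and finally calibration so each gene's geometric mean over samples is 1
#' (CNRQ).  Missing Cq values propagate to missing CNRQ (complete-case
#' behaviour); every sample must quantify at least one reference gene.
#'
#' @param cq Numeric matrix, samples x genes, of quantification cycles;
#'   dimnames required.
#' @param reference_genes Character vector of reference-gene column names.
#' @param efficiency Amplification efficiency per cycle; 2 means perfect
#'   doubling.  Either a scalar or a named per-gene vector.
#' @return Object of class `cnrq_result`: list with `cnrq` (samples x
#'   genes), `nf` (per-sample normalisation factors), `reference_genes`.
#' @export
cnrq <- function(cq, reference_genes, efficiency = 2.0) {
  stopifnot(is.matrix(cq), is.numeric(cq),
            !is.null(rownames(cq)), !is.null(colnames(cq)))
  if (!all(reference_genes %in% colnames(cq)))
    stop("reference genes missing from Cq table: ",
         paste(setdiff(reference_genes, colnames(cq)), collapse = ", "))
  eff <- if (length(efficiency) == 1L)
    setNames(rep(efficiency, ncol(cq)), colnames(cq))
  else efficiency[colnames(cq)]
  if (any(is.na(eff) | eff <= 1))
    stop("efficiencies must be > 1 and cover every gene")
  mean_cq <- colMeans(cq, na.rm = TRUE)
  rq <- sweep(cq, 2L, mean_cq, function(x, m) m - x)
  rq <- sweep(rq, 2L, log(eff), `*`)          # log RQ
  ref_log <- rq[, reference_genes, drop = FALSE]
  nf_log <- rowMeans(ref_log, na.rm = TRUE)   # log geometric mean
  if (any(!is.finite(nf_log)))
    stop("sample(s) without any reference-gene Cq: ",
         paste(rownames(cq)[!is.finite(nf_log)], collapse = ", "))
  nrq_log <- sweep(rq, 1L, nf_log, `-`)
  cal_log <- colMeans(nrq_log, na.rm = TRUE)
  cnrq_log <- sweep(nrq_log, 2L, cal_log, `-`)
  structure(list(cnrq = exp(cnrq_log), nf = exp(nf_log),
                 reference_genes = reference_genes),
            class = "cnrq_result")
}

#' @export
print.cnrq_result <- function(x, digits = 3, ...) {
  cat("CNRQ table: ", nrow(x$cnrq), " samples x ", ncol(x$cnrq),
      " genes (references: ", paste(x$reference_genes, collapse = ", "),
      ")\n", sep = "")
  print(round(head(x$cnrq), digits))
  invisible(x)
}

#' Spearman rank correlation with complete-case handling
#'
#' Pairs with a missing value in either vector are dropped first.  rho is
#' the Pearson correlation of average-tie ranks.  The two-sided p-value
#' uses the t approximation for n > 10 and exhaustive permutation of one
#' rank vector for n <= 10.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p`, `n` (complete pairs used).
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs (n = ", n, ")")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    stop("constant vector after ranking; rho undefined")
  rho <- cor(rx, ry)
  if (n > 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
  } else {
    # exhaustive permutation null: with fixed rank marginals, rho is a
    # monotone function of sum(rx[perm] * ry), so tail areas transfer
    perms <- all_permutations(n)
    stat <- as.vector(matrix(rx[perms], nrow(perms)) %*% ry)
    obs <- sum(rx * ry)
    mu <- mean(stat)
    p <- mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

# all permutations of 1..n as an n! x n matrix of index vectors
all_permutations <- function(n) {
  stopifnot(n <= 10L)
  p <- matrix(1L, 1L, 1L)
  for (k in 2:n) {
    blocks <- lapply(seq_len(k), function(pos) {
      left <- if (pos > 1L) p[, seq_len(pos - 1L), drop = FALSE]
      right <- if (pos <= ncol(p)) p[, pos:ncol(p), drop = FALSE]
      cbind(left, matrix(k, nrow(p), 1L), right)
    })
    p <- do.call(rbind, blocks)
  }
  p
}
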