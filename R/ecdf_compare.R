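#' Split fold changes by seed class
#'
#' Partitions per-gene log2 fold changes into the four seed classes
#' (`CS_only`, `IS_only`, `both`, `neither`) given a seed-class annotation
#' (from [classify_genes()]; the annotation's word sets should include the
#' +1 shifted variants when 5'-truncated isomiRs are active).
#'
#' @param records Output of [per_gene_stats()] (needs `gene_id`,
#'   `log2fc`).
#' @param annotations Output of [classify_genes()].
#' @return Named list of four `class_distribution` objects (lists with
#'   `cls`, `values`, `n`).
#' @export
build_class_distributions <- function(records, annotations) {
  missing <- setdiff(records$gene_id, annotations$gene_id)
  if (length(missing))
    stop("genes without annotation: ",
         paste(head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  cls <- annotations$cls[match(records$gene_id, annotations$gene_id)]
  if (any(!is.finite(records$log2fc)))
    stop("non-finite log2fc values")
  out <- lapply(levels(cls), function(cl) {
    v <- records$log2fc[cls == cl]
    structure(list(cls = cl, values = v, n = length(v)),
              class = "class_distribution")
  })
  names(out) <- levels(cls)
  out
}

#' Evaluate an empirical cumulative distribution function
#'
#' Right-continuous step function: the fraction of values `<= x`.
#'
#' @param values Non-empty numeric vector.
#' @param x Evaluation point(s).
#' @return `F(x)`, vectorised over `x`.
#' @export
ecdf_eval <- function(values, x) {
  if (!length(values)) stop("empty value vector")
  vapply(x, function(q) mean(values <= q), numeric(1))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two ECDFs.  The default
#' p-value uses the asymptotic Kolmogorov distribution on
#' `sqrt(na*nb/(na+nb)) * D`; `exact = TRUE` enumerates all label
#' assignments instead (feasible for small samples only) and returns
#' `P(D* >= D)` under exchangeability.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param exact Use exhaustive label-permutation enumeration
#'   (requires `choose(na+nb, na) <= 1e6`).
#' @return List with `D`, `p`, `method`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  D <- ks_D(a, b)
  if (exact) {
    n <- length(a) + length(b)
    if (choose(n, length(a)) > 1e6)
      stop("exact enumeration infeasible for these sample sizes")
    pool <- c(a, b)
    idx <- combn(n, length(a))
    Ds <- apply(idx, 2L, function(ia) ks_D(pool[ia], pool[-ia]))
    p <- mean(Ds >= D - 1e-12)
    method <- "exact label permutation"
  } else {
    ne <- length(a) * length(b) / (length(a) + length(b))
    p <- kolmogorov_sf(sqrt(ne) * D)
    method <- "asymptotic Kolmogorov"
  }
  list(D = D, p = p, method = method)
}

ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf_eval(a, grid) - ecdf_eval(b, grid)))
}

# survival function of the Kolmogorov distribution, 2*sum (-1)^(k-1) exp(-2 k^2 t^2)
kolmogorov_sf <- function(t) {
  if (t < 0.05) return(1)
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Mean (or median) fold-change shift of a seed class
#'
#' The location difference between a seed-containing class and the
#' `neither` background, the scalar summary of the leftward ECDF shift
#' repression produces.
#'
#' @param cls_values log2 fold changes of the seed class.
#' @param neither_values log2 fold changes of the `neither` class.
#' @param stat `"mean"` (default) or `"median"`.
#' @return Numeric shift (negative = class more repressed).
#' @export
class_shift <- function(cls_values, neither_values,
                        stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else median
  f(cls_values) - f(neither_values)
}

#' Additivity gap between single- and double-seed repression
#'
#' If canonical- and internal-seed repression combine additively, the shift
#' of the `both` class equals the sum of the two single-class shifts.  The
#' gap `both - (CS + IS)` is reported with a seeded percentile bootstrap
#' confidence interval (classes resampled independently).
#'
#' @param cs_values,is_values,both_values,neither_values Per-class log2
#'   fold changes.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap (default 1).
#' @param stat Location statistic, as in [class_shift()].
#' @return List with `gap`, `ci` (length 2), `n_boot`, and the three
#'   observed shifts.
#' @export
additivity_gap <- function(cs_values, is_values, both_values,
                           neither_values, n_boot = 1000L, conf = 0.95,
                           seed = 1L, stat = "mean") {
  shifts <- function(cs, is_, bo, ne)
    c(cs = class_shift(cs, ne, stat), is = class_shift(is_, ne, stat),
      both = class_shift(bo, ne, stat))
  obs <- shifts(cs_values, is_values, both_values, neither_values)
  gap <- unname(obs["both"] - obs["cs"] - obs["is"])
  set.seed(seed)
  gaps <- replicate(n_boot, {
    s <- shifts(sample(cs_values, replace = TRUE),
                sample(is_values, replace = TRUE),
                sample(both_values, replace = TRUE),
                sample(neither_values, replace = TRUE))
    unname(s["both"] - s["cs"] - s["is"])
  })
  alpha <- (1 - conf) / 2
  list(gap = gap, ci = unname(quantile(gaps, c(alpha, 1 - alpha))),
       n_boot = n_boot, shifts = obs)
}
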