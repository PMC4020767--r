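# pair coding shared by the DP and the structure scorer
.PAIR_CODES <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Load a nearest-neighbour duplex parameter set
#'
#' Reads stacking energies (6 x 6 over the pair alphabet AU/UA/CG/GC and
#' the GU/UG wobbles), the duplex initiation penalty, and bulge /
#' internal-loop penalties by total unpaired size from a plain-text table.
#' The default is the table shipped with the package; a fuller Turner-style
#' table in the same format can be swapped in.
#'
#' @param path Parameter TSV (default: the bundled table).
#' @return Object of class `nn_parameter_set`: list with `stacks` (6 x 6
#'   named matrix), `init`, `bulge`, `internal` (penalty vectors indexed by
#'   size), `max_loop_side` (10), `version`.
#' @export
nn_params <- function(path = system.file("extdata", "nn_params.tsv",
                                         package = "bimodalseed")) {
  if (!nzchar(path) || !file.exists(path))
    stop("parameter file not found: ", path)
  hdr <- readLines(path, n = 1L)
  version <- sub("^#\\s*version:\\s*", "", hdr)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stacks <- matrix(NA_real_, 6L, 6L,
                   dimnames = list(.PAIR_CODES, .PAIR_CODES))
  st <- tab[tab$term == "stack", ]
  stacks[cbind(st$a, st$b)] <- st$value
  if (anyNA(stacks)) stop("incomplete stack table in ", path)
  bu <- tab[tab$term == "bulge", ]
  bulge <- setNames(bu$value, bu$a)[as.character(seq_len(max(as.integer(bu$a))))]
  il <- tab[tab$term == "internal", ]
  internal <- setNames(il$value, il$a)
  internal <- internal[as.character(2:max(as.integer(il$a)))]
  if (anyNA(bulge) || anyNA(internal))
    stop("gaps in loop-penalty tables in ", path)
  if (any(bulge < 0) || any(internal < 0) ||
      is.unsorted(bulge) || is.unsorted(internal))
    stop("loop penalties must be >= 0 and nondecreasing in size")
  init <- tab$value[tab$term == "init"]
  if (length(init) != 1L) stop("missing init term in ", path)
  structure(list(stacks = stacks, init = init, bulge = unname(bulge),
                 internal = setNames(unname(internal),
                                     2:(length(internal) + 1L)),
                 max_loop_side = 10L, version = version),
            class = "nn_parameter_set")
}

#' @export
print.nn_parameter_set <- function(x, ...) {
  cat("nearest-neighbour duplex parameters (", x$version, ")\n",
      "  init ", x$init, " kcal/mol; bulge 1-", length(x$bulge),
      "; internal 2-", length(x$internal) + 1L, "\n", sep = "")
  invisible(x)
}

# normalise to uppercase RNA; DNA input is transcribed T->U
as_rna_chars <- function(seq) {
  s <- chartr("T", "U", toupper(seq))
  if (grepl("[^ACGU]", s))
    stop("sequence contains characters outside ACGU/ACGT: ", seq)
  strsplit(s, "")[[1]]
}

# pair code index (1..6) or 0 if the two nucleotides cannot pair
pair_code <- function(x, y) {
  match(paste0(x, y), .PAIR_CODES, nomatch = 0L)
}

# internal: loop cost template for gap sizes (ka, kb) in 0..L each,
# excluding the stacked (0,0) cell; Inf where no term applies
loop_template <- function(params) {
  L <- params$max_loop_side
  tm <- matrix(Inf, L + 1L, L + 1L)
  for (ka in 0:L) for (kb in 0:L) {
    if (ka == 0L && kb == 0L) next
    s <- ka + kb
    tm[ka + 1L, kb + 1L] <-
      if (ka == 0L || kb == 0L) params$bulge[s]
      else params$internal[as.character(s)]
  }
  tm
}

#' Minimum-free-energy intermolecular RNA duplex
#'
#' Global minimum over all non-crossing antiparallel pairings of the two
#' strands under a nearest-neighbour model: Watson-Crick and GU wobble
#' pairs, stacking energies for adjacent pairs, bulge and internal-loop
#' penalties for interrupted helices (each side capped at 10 unpaired
#' nucleotides per loop), and a single duplex initiation penalty.  No
#' intramolecular structure, dangling ends or temperature scaling.
#' Traceback ties are broken toward the larger pair count, then by a fixed
#' candidate order (stacked predecessor first, then loops by increasing
#' size), making the reported structure deterministic.
#'
#' @param mirna_seq Guide sequence 5'->3' (RNA; DNA is transcribed), or a
#'   [mature_mirna].
#' @param target_seq Target window 5'->3' (DNA or RNA), length <= 60.
#' @param params An [nn_params()] parameter set.
#' @return Object of class `duplex_result`: list with `energy` (kcal/mol;
#'   `Inf` when no pair can form), `pairing` (data.frame `mirna_pos`,
#'   `target_pos`, 1-based, 5'->3' on the guide), `max_run` (longest
#'   stretch of consecutively stacked pairs) and `n_pairs`.
#' @export
#' @examples
#' duplex_mfe("GGGG", "CCCC")$energy   # init + 3 GC/GC stacks
duplex_mfe <- function(mirna_seq, target_seq, params = nn_params()) {
  if (inherits(mirna_seq, "mature_mirna")) mirna_seq <- mirna_seq$sequence
  a <- as_rna_chars(mirna_seq)
  b <- as_rna_chars(target_seq)
  n <- length(a); m <- length(b)
  if (n > 60L || m > 60L) stop("duplex sequences must be <= 60 nt")
  pc <- outer(seq_len(n), seq_len(m),
              function(i, j) pair_code(a[i], b[j]))
  if (all(pc == 0L)) return(empty_duplex())
  L <- params$max_loop_side
  tmpl <- loop_template(params)
  D <- matrix(Inf, n, m)
  NP <- matrix(0L, n, m)
  for (i in seq_len(n)) for (j in rev(seq_len(m))) {
    if (pc[i, j] == 0L) next
    best <- params$init; bestnp <- 1L
    # stacked predecessor
    if (i > 1L && j < m && pc[i - 1L, j + 1L] > 0L &&
        is.finite(D[i - 1L, j + 1L])) {
      e <- D[i - 1L, j + 1L] + params$stacks[pc[i - 1L, j + 1L], pc[i, j]]
      if (e < best - 1e-9 ||
          (abs(e - best) <= 1e-9 && NP[i - 1L, j + 1L] + 1L > bestnp)) {
        best <- min(e, best); bestnp <- NP[i - 1L, j + 1L] + 1L
      }
    }
    # loop-closing predecessors
    if (i > 1L && j < m) {
      i0r <- seq.int(max(1L, i - 1L - L), i - 1L)
      j0r <- seq.int(j + 1L, min(m, j + 1L + L))
      sub <- D[i0r, j0r, drop = FALSE]
      ka <- i - i0r - 1L; kb <- j0r - j - 1L
      cost <- tmpl[cbind(rep(ka + 1L, length(kb)),
                         rep(kb + 1L, each = length(ka)))]
      cand <- sub + matrix(cost, length(i0r), length(j0r))
      fin <- is.finite(cand)
      if (any(fin)) {
        cmin <- min(cand[fin])
        if (cmin < best - 1e-9) {
          hits <- which(fin & abs(cand - cmin) <= 1e-9, arr.ind = TRUE)
          best <- cmin
          bestnp <- max(NP[cbind(i0r[hits[, 1L]], j0r[hits[, 2L]])]) + 1L
        } else if (abs(cmin - best) <= 1e-9) {
          hits <- which(fin & abs(cand - cmin) <= 1e-9, arr.ind = TRUE)
          np <- max(NP[cbind(i0r[hits[, 1L]], j0r[hits[, 2L]])]) + 1L
          if (np > bestnp) bestnp <- np
        }
      }
    }
    D[i, j] <- best; NP[i, j] <- bestnp
  }
  if (!any(is.finite(D))) return(empty_duplex())
  emin <- min(D[is.finite(D)])
  ends <- which(is.finite(D) & abs(D - emin) <= 1e-9, arr.ind = TRUE)
  # tie-break: max pairs, then smallest guide pos, then largest target pos
  o <- order(-NP[ends], ends[, 1L], -ends[, 2L])
  end <- ends[o[1L], ]
  pairing <- traceback_duplex(end[1L], end[2L], D, NP, pc, params, tmpl, m)
  res <- structure(list(energy = emin, pairing = pairing,
                        n_pairs = nrow(pairing),
                        max_run = run_lengths_max(pairing)),
                   class = "duplex_result")
  res
}

empty_duplex <- function() {
  structure(list(energy = Inf,
                 pairing = data.frame(mirna_pos = integer(),
                                      target_pos = integer()),
                 n_pairs = 0L, max_run = 0L),
            class = "duplex_result")
}

traceback_duplex <- function(i, j, D, NP, pc, params, tmpl, m) {
  L <- params$max_loop_side
  path <- list()
  repeat {
    path[[length(path) + 1L]] <- c(i, j)
    target_e <- D[i, j]; target_np <- NP[i, j]
    nxt <- NULL
    # candidates in deterministic preference order: stack, then loops by
    # increasing total size, smaller guide gap first
    if (i > 1L && j < m && pc[i - 1L, j + 1L] > 0L &&
        is.finite(D[i - 1L, j + 1L]) &&
        abs(D[i - 1L, j + 1L] +
            params$stacks[pc[i - 1L, j + 1L], pc[i, j]] - target_e) <= 1e-9 &&
        NP[i - 1L, j + 1L] + 1L == target_np) {
      nxt <- c(i - 1L, j + 1L)
    }
    if (is.null(nxt)) {
      gaps <- expand.grid(ka = 0:L, kb = 0:L)
      gaps <- gaps[gaps$ka + gaps$kb > 0L, ]
      gaps <- gaps[order(gaps$ka + gaps$kb, gaps$ka), ]
      for (g in seq_len(nrow(gaps))) {
        i0 <- i - gaps$ka[g] - 1L; j0 <- j + gaps$kb[g] + 1L
        if (i0 < 1L || j0 > m) next
        cost <- tmpl[gaps$ka[g] + 1L, gaps$kb[g] + 1L]
        if (!is.finite(cost) || !is.finite(D[i0, j0])) next
        if (abs(D[i0, j0] + cost - target_e) <= 1e-9 &&
            NP[i0, j0] + 1L == target_np) { nxt <- c(i0, j0); break }
      }
    }
    if (is.null(nxt)) break  # opening pair reached
    i <- nxt[1L]; j <- nxt[2L]
  }
  pr <- do.call(rbind, rev(path))
  data.frame(mirna_pos = pr[, 1L], target_pos = pr[, 2L])
}

run_lengths_max <- function(pairing) {
  if (!nrow(pairing)) return(0L)
  runs <- pairing_runs(pairing)
  max(runs$length)
}

# maximal stacked runs: start index into the pairing plus run length
pairing_runs <- function(pairing) {
  np <- nrow(pairing)
  stacked <- diff(pairing$mirna_pos) == 1L & diff(pairing$target_pos) == -1L
  starts <- c(1L, which(!stacked) + 1L)
  ends <- c(which(!stacked), np)
  data.frame(start = starts, end = ends, length = ends - starts + 1L)
}

#' @export
print.duplex_result <- function(x, ...) {
  if (!is.finite(x$energy)) {
    cat("duplex: no admissible pairing\n")
  } else {
    cat("duplex MFE ", format(x$energy, digits = 4), " kcal/mol, ",
        x$n_pairs, " pairs, longest stacked run ", x$max_run, "\n",
        sep = "")
  }
  invisible(x)
}

#' Longest uninterrupted base-paired stretch of a duplex
#'
#' Length of the longest run of pairs consecutive on both strands in the
#' reported structure; 0 for an empty pairing.
#'
#' @param result A [duplex_mfe()] result.
#' @return Integer run length.
#' @export
max_contiguous_run <- function(result) {
  stopifnot(inherits(result, "duplex_result"))
  result$max_run
}

#' Does a duplex contain a long run at the seed window?
#'
#' Checks whether the structure has an uninterrupted stacked run of at
#' least `run_min` pairs that includes the (shift-adjusted) seed window:
#' at least `min_overlap` guide positions of the run fall inside the
#' window.  The default of 1 is deliberate: a global MFE structure may
#' trade a terminal pair of a long planted helix against chance
#' complementarity elsewhere in the window, so requiring the run to span
#' every seed position would miss genuinely extended hybrids.
#'
#' @param result A [duplex_mfe()] result.
#' @param seed A [seed_definition()].
#' @param run_min Minimum run length (default 10).
#' @param min_overlap Minimum guide positions of the window inside the
#'   run (default 4).
#' @return Logical scalar.
#' @export
long_run_covers_seed <- function(result, seed, run_min = 10L,
                                 min_overlap = 4L) {
  stopifnot(inherits(result, "duplex_result"),
            inherits(seed, "seed_definition"))
  if (!nrow(result$pairing)) return(FALSE)
  w <- seed_window(seed)
  runs <- pairing_runs(result$pairing)
  runs <- runs[runs$length >= run_min, , drop = FALSE]
  if (!nrow(runs)) return(FALSE)
  for (r in seq_len(nrow(runs))) {
    pos <- result$pairing$mirna_pos[runs$start[r]:runs$end[r]]
    if (sum(pos >= w[1] & pos <= w[2]) >= min_overlap) return(TRUE)
  }
  FALSE
}

#' Score a given duplex pairing
#'
#' Evaluates the nearest-neighbour energy of an explicit non-crossing
#' pairing (initiation + stacks + loop penalties), independent of the DP.
#' Used as the structure scorer for enumeration-based checks; returns
#' `Inf` for pairings with an inadmissible pair or an over-long loop.
#'
#' @param mirna_seq,target_seq Sequences as in [duplex_mfe()].
#' @param pairing `data.frame` with `mirna_pos`, `target_pos` (1-based),
#'   ordered by increasing `mirna_pos`.
#' @param params An [nn_params()] set.
#' @return Energy in kcal/mol.
#' @export
duplex_energy_of_pairing <- function(mirna_seq, target_seq, pairing,
                                     params = nn_params()) {
  if (inherits(mirna_seq, "mature_mirna")) mirna_seq <- mirna_seq$sequence
  a <- as_rna_chars(mirna_seq); b <- as_rna_chars(target_seq)
  np <- nrow(pairing)
  if (np == 0L) return(Inf)
  if (any(diff(pairing$mirna_pos) <= 0L) ||
      any(diff(pairing$target_pos) >= 0L))
    stop("pairing must be strictly monotone (no crossings)")
  codes <- pair_code(a[pairing$mirna_pos], b[pairing$target_pos])
  if (any(codes == 0L)) return(Inf)
  e <- params$init
  L <- params$max_loop_side
  if (np > 1L) for (s in seq_len(np - 1L)) {
    ka <- pairing$mirna_pos[s + 1L] - pairing$mirna_pos[s] - 1L
    kb <- pairing$target_pos[s] - pairing$target_pos[s + 1L] - 1L
    if (ka > L || kb > L) return(Inf)
    e <- e + if (ka == 0L && kb == 0L)
      params$stacks[codes[s], codes[s + 1L]]
    else if (ka == 0L || kb == 0L) params$bulge[ka + kb]
    else params$internal[[as.character(ka + kb)]]
  }
  unname(e)
}

#' Duplex-energy screen of internal-seed target windows
#'
#' For every gene in the down-regulated and unaffected sets that has at
#' least one seed match, extracts the window `match +/- window_flank`,
#' computes the duplex MFE of the guide against each window, and reports
#' the per-gene minimum.  Hybrids whose structure contains an
#' uninterrupted run of at least `run_min` pairs covering the full seed
#' window are flagged as candidate extended (centered-site-like) motifs.
#'
#' @param mirna A [mature_mirna] (or sequence).
#' @param utrs Named character vector / `DNAStringSet` of 3'UTRs.
#' @param matches `data.frame` from [scan_utr()] for the seed word(s) being
#'   screened.
#' @param seed The [seed_definition()] whose guide window the long-run flag
#'   must cover.
#' @param down_set,unaffected_set Character vectors of gene ids (e.g. from
#'   [stratify_by_t()]).
#' @param window_flank Context either side of the match (default 15 nt).
#' @param run_min Long-run threshold (default 10).
#' @param params An [nn_params()] set.
#' @param energy_cut Optional energy threshold; when given, per-group
#'   subsets below the cut are also returned.
#' @return List with `down` and `unaffected` (data.frames `gene_id`,
#'   `energy`, `max_run`, `covers_seed`), `flagged` (gene ids with a
#'   qualifying long run), `per_site` (per-window detail).
#' @export
screen_targets <- function(mirna, utrs, matches, seed, down_set,
                           unaffected_set, window_flank = 15L,
                           run_min = 10L, params = nn_params(),
                           energy_cut = NULL) {
  stopifnot(inherits(seed, "seed_definition"))
  seqs <- as_utr_set(utrs)
  groups <- list(down = down_set, unaffected = unaffected_set)
  per_site <- list()
  out <- list()
  flagged <- character()
  for (gname in names(groups)) {
    genes <- groups[[gname]]
    rows <- list()
    for (g in genes) {
      mt <- matches[matches$gene_id == g, , drop = FALSE]
      if (!nrow(mt)) {
        message("screen_targets: gene ", g, " has no seed match; skipped")
        next
      }
      s <- as.character(seqs[[g]])
      best <- NULL
      for (r in seq_len(nrow(mt))) {
        k <- nchar(mt$word[r])
        from <- max(1L, mt$start[r] + 1L - window_flank)
        to <- min(nchar(s), mt$start[r] + k + window_flank)
        win <- substr(s, from, to)
        dx <- duplex_mfe(mirna, win, params)
        cov <- long_run_covers_seed(dx, seed, run_min)
        per_site[[length(per_site) + 1L]] <- data.frame(
          gene_id = g, group = gname, window_start = from - 1L,
          window_end = to, energy = dx$energy, max_run = dx$max_run,
          covers_seed = cov, stringsAsFactors = FALSE)
        if (is.null(best) || dx$energy < best$energy ||
            (dx$energy == best$energy && cov && !best$covers_seed))
          best <- list(energy = dx$energy, max_run = dx$max_run,
                       covers_seed = cov)
        if (cov) flagged <- union(flagged, g)
      }
      rows[[g]] <- data.frame(gene_id = g, energy = best$energy,
                              max_run = best$max_run,
                              covers_seed = best$covers_seed,
                              stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(), energy = numeric(),
                 max_run = integer(), covers_seed = logical())
    rownames(df) <- NULL
    out[[gname]] <- df
  }
  res <- list(down = out$down, unaffected = out$unaffected,
              flagged = sort(flagged),
              per_site = if (length(per_site)) do.call(rbind, per_site)
                         else NULL)
  if (!is.null(energy_cut))
    res$stable <- lapply(out, function(df)
      df$gene_id[is.finite(df$energy) & df$energy <= energy_cut])
  res
}
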