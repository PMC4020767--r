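# independent oracles and small fixtures used across the suite

# naive character-by-character overlapping substring search, 0-based
naive_scan <- function(utr, word) {
  k <- nchar(word)
  n <- nchar(utr)
  if (n < k) return(integer())
  hits <- integer()
  for (s in 0:(n - k)) {
    ok <- TRUE
    for (t in seq_len(k)) {
      cu <- substr(utr, s + t, s + t)
      cw <- substr(word, t, t)
      if (cu == "N" || cu != cw) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_utr <- function(len, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  paste(sample(alph, len, TRUE, prob = prob), collapse = "")
}

random_word <- function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE),
                                 collapse = "")

# exhaustive minimum over all non-crossing antiparallel pairings, using
# the explicit structure scorer (independent of the DP recurrence)
oracle_duplex_mfe <- function(a, b, params = nn_params()) {
  n <- nchar(a); m <- nchar(b)
  best <- Inf
  for (k in seq_len(min(n, m))) {
    ai <- if (k == 1) matrix(seq_len(n), 1) else utils::combn(n, k)
    bj <- if (k == 1) matrix(seq_len(m), 1) else utils::combn(m, k)
    for (ci in seq_len(ncol(ai))) for (cj in seq_len(ncol(bj))) {
      pr <- data.frame(mirna_pos = ai[, ci],
                       target_pos = rev(bj[, cj]))
      e <- duplex_energy_of_pairing(a, b, pr, params)
      if (e < best) best <- e
    }
  }
  best
}

# small, fast generator configuration for unit tests
tiny_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 150L, utr_len_meanlog = 5.6, utr_len_sdlog = 0.4,
               utr_len_min = 80L, utr_len_max = 600L, master_seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
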