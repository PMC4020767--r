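test_that("parameter table satisfies its thermodynamic invariants", {
  p <- nn_params()
  wc <- c("AU", "UA", "CG", "GC")
  expect_true(all(p$stacks[wc, wc] <= 0))
  expect_true(all(p$bulge >= 0) && !is.unsorted(p$bulge))
  expect_true(all(p$internal >= 0) && !is.unsorted(p$internal))
  # step-reversal symmetry: reading a stack from the other strand
  swap <- function(pr) paste0(substr(pr, 2, 2), substr(pr, 1, 1))
  for (p1 in rownames(p$stacks)) for (p2 in colnames(p$stacks))
    expect_equal(p$stacks[p1, p2], p$stacks[swap(p2), swap(p1)])
  # replacing an A-U by the G-C pair never destabilises the step
  for (p2 in colnames(p$stacks)) {
    expect_lte(p$stacks["GC", p2], p$stacks["AU", p2])
    expect_lte(p$stacks["CG", p2], p$stacks["UA", p2])
  }
  for (p1 in rownames(p$stacks)) {
    expect_lte(p$stacks[p1, "GC"], p$stacks[p1, "AU"])
    expect_lte(p$stacks[p1, "CG"], p$stacks[p1, "UA"])
  }
})

test_that("simple duplexes have closed-form energies", {
  p <- nn_params()
  d <- duplex_mfe("GGGG", "CCCC", p)
  expect_equal(d$energy, p$init + 3 * p$stacks["GC", "GC"])
  expect_equal(d$n_pairs, 4L)
  expect_equal(d$max_run, 4L)
  # no complementarity at all -> sentinel
  s <- duplex_mfe("AAAA", "AAAA", p)
  expect_equal(s$energy, Inf)
  expect_equal(nrow(s$pairing), 0L)
  expect_equal(max_contiguous_run(s), 0L)
})

test_that("duplex is symmetric under swapping the two strands", {
  set.seed(51)
  for (i in 1:25) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(5:12, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(5:12, 1), TRUE),
               collapse = "")
    expect_equal(duplex_mfe(a, b)$energy, duplex_mfe(b, a)$energy,
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("DP equals exhaustive enumeration on random short pairs", {
  set.seed(52)
  p <- nn_params()
  for (i in 1:40) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(4:7, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(4:7, 1), TRUE),
               collapse = "")
    expect_equal(duplex_mfe(a, b, p)$energy, oracle_duplex_mfe(a, b, p),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("reported structures score back to the reported energy", {
  set.seed(53)
  p <- nn_params()
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "U"), 15, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
    d <- duplex_mfe(a, b, p)
    if (!is.finite(d$energy)) next
    expect_equal(duplex_energy_of_pairing(a, b, d$pairing, p), d$energy,
                 tolerance = 1e-9)
    # structure is strictly monotone (no crossings)
    expect_true(all(diff(d$pairing$mirna_pos) > 0))
    expect_true(all(diff(d$pairing$target_pos) < 0))
    expect_lte(d$max_run, d$n_pairs)
  }
})

test_that("unpairable flanks never raise the MFE", {
  set.seed(54)
  for (i in 1:15) {
    a <- paste(sample(c("A", "C", "G", "U"), 10, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")
    e0 <- duplex_mfe(a, b)$energy
    e1 <- duplex_mfe(a, paste0("AAAA", b, "AAAA"))$energy
    if (is.finite(e0)) expect_lte(e1, e0 + 1e-9)
  }
})

test_that("contiguous runs are measured on both strands", {
  # perfect 7-bp duplex
  d <- duplex_mfe("GGGGGGG", "CCCCCCC")
  expect_equal(max_contiguous_run(d), 7L)
  # bulge splits the helix 4 + 3: GGGG-A-GGG vs complement without the A
  d2 <- duplex_mfe("GGGGAGGG", "CCCCCCC")
  expect_equal(sort(bimodalseed:::pairing_runs(d2$pairing)$length,
                    decreasing = TRUE)[1:2], c(4L, 3L))
  expect_equal(max_contiguous_run(d2), 4L)
})

test_that("long-run detection anchors on the seed window", {
  mir <- mature_mirna("m", "UAGAAUCUUGCACUCGGCCUUUCCA")
  seed <- seed_definition("IS", 6, 7)
  # perfect complement of guide positions 6-17 -> 12-run over the seed
  ext <- chartr("U", "T", as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(substr(mir$sequence, 6, 17)))))
  d <- duplex_mfe(mir, paste0("AAAA", ext, "AAAA"))
  expect_gte(d$max_run, 12L)
  expect_true(long_run_covers_seed(d, seed))
  # the plain 7-mer site alone cannot yield a 10-run
  w7 <- chartr("U", "T", as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(substr(mir$sequence, 6, 12)))))
  d7 <- duplex_mfe(mir, paste0("AAAA", w7, "AAAA"))
  expect_false(long_run_covers_seed(d7, seed))
})

test_that("screen_targets separates groups and flags planted hybrids", {
  cfg <- tiny_config(seed = 55, f_cs = 0, f_both = 0, f_is = 0.3,
                     extended_fraction = 0.2)
  sim <- sim_all(cfg, dir = NULL)
  tr <- sim$truth
  m <- scan_utr(sim$utrs, c(cfg$words$cs, cfg$words$is))
  ism <- m[m$seed_name == "IS", , drop = FALSE]
  isg <- unique(ism$gene_id)
  half <- isg[seq_len(length(isg) %/% 2)]
  sc <- screen_targets(cfg$mirna, sim$utrs, ism,
                       seed_definition("IS", 6, 7),
                       down_set = half, unaffected_set = setdiff(isg, half))
  expect_setequal(c(sc$down$gene_id, sc$unaffected$gene_id), isg)
  expect_true(all(is.finite(sc$down$energy)))
  expect_setequal(sc$flagged, tr$gene_id[tr$extended])
  # empty down set -> empty frame, not an error
  sc0 <- screen_targets(cfg$mirna, sim$utrs, ism,
                        seed_definition("IS", 6, 7),
                        down_set = character(), unaffected_set = half)
  expect_equal(nrow(sc0$down), 0L)
  # genes without matches are skipped with a message
  expect_message(
    screen_targets(cfg$mirna, sim$utrs, ism, seed_definition("IS", 6, 7),
                   down_set = tr$gene_id[tr$cls == "neither"][1],
                   unaffected_set = character()),
    "no seed match")
})
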