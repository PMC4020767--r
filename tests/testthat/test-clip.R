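gr_reads <- function(gene, start0, width = 10L, count = 1L) {
  GenomicRanges::GRanges(gene, IRanges::IRanges(start0 + 1L,
                                                width = width),
                         strand = "+", count = count)
}

test_that("seed windows extend, clip and merge per seed type", {
  m <- data.frame(gene_id = "tx1", word = "GAGGTCA", seed_name = "IS",
                  start = 100L)
  w <- seed_windows(m, c(tx1 = 500L), flank = 10)
  expect_equal(GenomicRanges::start(w) - 1L, 90L)   # 0-based 90
  expect_equal(GenomicRanges::end(w), 117L)         # half-open end 117

  # clipped at the transcript start
  m0 <- data.frame(gene_id = "tx1", word = "GAGGTCA", seed_name = "IS",
                   start = 0L)
  w0 <- seed_windows(m0, c(tx1 = 500L), flank = 10)
  expect_equal(GenomicRanges::start(w0), 1L)

  # same-type windows 5 nt apart merge; different types never merge
  m2 <- data.frame(gene_id = "tx1",
                   word = c("GAGGTCA", "GAGGTCA", "TCAGCAT"),
                   seed_name = c("IS", "IS", "CS"),
                   start = c(100L, 105L, 103L))
  w2 <- seed_windows(m2, c(tx1 = 500L), flank = 10)
  expect_equal(length(w2), 2L)
  expect_setequal(S4Vectors::mcols(w2)$seed_type, c("IS", "CS"))
})

test_that("overlap counting matches a naive oracle", {
  set.seed(61)
  for (rep in 1:10) {
    wins <- GenomicRanges::GRanges("tx",
      IRanges::IRanges(start = sample(1:400, 15), width = 27),
      seed_type = "IS")
    reads <- gr_reads("tx", sample(0:420, 50, TRUE), width = 20,
                      count = sample(1:3, 50, TRUE))
    got <- count_overlaps(wins, reads)
    naive <- vapply(seq_along(wins), function(i) {
      s <- GenomicRanges::start(wins)[i]; e <- GenomicRanges::end(wins)[i]
      sum(S4Vectors::mcols(reads)$count[
        GenomicRanges::start(reads) <= e & GenomicRanges::end(reads) >= s])
    }, 0L)
    expect_equal(got, naive)
  }
  expect_equal(count_overlaps(GenomicRanges::GRanges(
    "tx", IRanges::IRanges(1, 10), seed_type = "IS"),
    GenomicRanges::GRanges()), 0L)
})

test_that("peak calling applies count, fold and pseudocount rules", {
  win <- GenomicRanges::GRanges("tx", IRanges::IRanges(101, 127),
                                seed_type = "IS")
  treat <- gr_reads("tx", rep(105L, 10))
  ctrl <- gr_reads("tx", rep(105L, 2))
  pk <- call_peaks(win, treat, ctrl, libsize_treat = 100,
                   libsize_ctrl = 100)
  expect_equal(pk$n_treat, 10L); expect_equal(pk$n_ctrl, 2L)
  expect_equal(pk$enrichment, (11 / 100) / (3 / 100))
  expect_true(pk$positive)

  # zero treatment reads -> negative regardless of control
  pk0 <- call_peaks(win, GenomicRanges::GRanges(), ctrl,
                    libsize_treat = 100, libsize_ctrl = 100)
  expect_false(pk0$positive)

  # equal normalised counts -> enrichment 1, negative at min_fold 2
  pk1 <- call_peaks(win, treat, treat, libsize_treat = 100,
                    libsize_ctrl = 100)
  expect_equal(pk1$enrichment, 1)
  expect_false(pk1$positive)

  # scaling both libraries leaves enrichment unchanged (pseudocount 0)
  pk2 <- call_peaks(win, treat, ctrl, libsize_treat = 100,
                    libsize_ctrl = 50, pseudocount = 0)
  pk3 <- call_peaks(win,
                    gr_reads("tx", rep(105L, 10), count = 3L),
                    gr_reads("tx", rep(105L, 2), count = 3L),
                    libsize_treat = 300, libsize_ctrl = 150,
                    pseudocount = 0)
  expect_equal(pk2$enrichment, pk3$enrichment)

  # read input order invariance
  set.seed(62)
  tr <- gr_reads("tx", sample(90:130, 30, TRUE))
  pkA <- call_peaks(win, tr, ctrl, libsize_treat = 100, libsize_ctrl = 100)
  pkB <- call_peaks(win, tr[sample(30)], ctrl, libsize_treat = 100,
                    libsize_ctrl = 100)
  expect_equal(pkA, pkB)

  # poisson mode reports a p-value
  pkP <- call_peaks(win, treat, ctrl, libsize_treat = 100,
                    libsize_ctrl = 100, test = "poisson")
  expect_true(all(c("p", "positive") %in% names(pkP)))
})

test_that("region annotation uses the midpoint and half-open junctions", {
  model <- data.frame(gene_id = "tx",
                      region = c("UTR5", "CDS", "UTR3"),
                      start = c(0L, 50L, 200L), end = c(50L, 200L, 400L))
  pk <- data.frame(gene_id = "tx", start = c(210L, 190L, 196L),
                   end = c(240L, 230L, 204L))
  ann <- annotate_region(pk, model)
  # midpoints 225, 210, 200: the junction midpoint (200) is downstream
  expect_equal(ann$region, c("UTR3", "UTR3", "UTR3"))
  pk2 <- data.frame(gene_id = "tx", start = 60L, end = 80L)
  expect_equal(annotate_region(pk2, model)$region, "CDS")
  expect_error(annotate_region(data.frame(gene_id = "tx", start = 500L,
                                          end = 600L), model),
               "outside")
})

test_that("expression overlap fractions are computed per seed type", {
  pk <- data.frame(gene_id = c("a", "b", "c", "d"),
                   seed_type = c("IS", "IS", "CS", "IS"),
                   region = c("UTR3", "UTR3", "UTR3", "CDS"),
                   positive = c(TRUE, TRUE, TRUE, TRUE))
  ov <- overlap_with_expression(pk, down_gene_set = c("a", "c"))
  expect_equal(ov$fraction[ov$seed_type == "IS"], 0.5)
  expect_equal(ov$fraction[ov$seed_type == "CS"], 1)
  ov0 <- overlap_with_expression(pk, down_gene_set = "zz")
  expect_equal(ov0$fraction, c(0, 0))
  # a seed type without positive UTR3 peaks is flagged as undefined
  pk$positive[3] <- FALSE
  expect_warning(ov2 <- overlap_with_expression(pk, "a"), "undefined")
  expect_true(is.na(ov2$fraction[ov2$seed_type == "CS"]))
})

test_that("caller recovers planted sites with high sensitivity", {
  # pooled over several small replicates: per-replicate site counts are
  # small enough that binomial noise would dominate a single draw
  tp <- 0L; n_true <- 0L
  for (s in 1:5) {
    cfg <- tiny_config(seed = 63 + s)
    sim <- sim_all(cfg, dir = NULL)
    m <- scan_utr(sim$utrs, c(cfg$words$cs, cfg$words$is))
    wins <- seed_windows(m, setNames(sim$truth$length, sim$truth$gene_id))
    pk <- call_peaks(wins, sim$clip$treat, sim$clip$ctrl)
    sites_gr <- GenomicRanges::GRanges(
      sim$clip$true_sites$gene_id,
      IRanges::IRanges(sim$clip$true_sites$start + 1L,
                       sim$clip$true_sites$end))
    pos_gr <- GenomicRanges::GRanges(
      pk$gene_id[pk$positive],
      IRanges::IRanges(pk$start[pk$positive] + 1L, pk$end[pk$positive]))
    tp <- tp + sum(IRanges::overlapsAny(sites_gr, pos_gr))
    n_true <- n_true + length(sites_gr)
    if (s == 1L) {
      # identical libraries produce no positives at fold >= 2
      pk_null <- call_peaks(wins, sim$clip$treat, sim$clip$treat)
      expect_equal(sum(pk_null$positive), 0L)
    }
  }
  expect_gte(tp / n_true, 0.9)
})
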