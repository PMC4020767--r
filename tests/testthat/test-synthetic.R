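test_that("generation is fully deterministic under the master seed", {
  cfg <- tiny_config(seed = 81, extended_fraction = 0.1)
  a <- sim_all(cfg, dir = NULL)
  b <- sim_all(cfg, dir = NULL)
  expect_identical(a$utrs, b$utrs)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expression$mat, b$expression$mat)
  expect_identical(a$qpcr$cq, b$qpcr$cq)
  expect_identical(as.data.frame(a$clip$treat), as.data.frame(b$clip$treat))
  # a different master seed changes the sequences
  c2 <- sim_all(tiny_config(seed = 82, extended_fraction = 0.1), dir = NULL)
  expect_false(identical(a$utrs, c2$utrs))
})

test_that("zero site frequencies guarantee word-free UTRs", {
  cfg <- tiny_config(seed = 83, f_cs = 0, f_is = 0, f_both = 0)
  ut <- gen_utrs(cfg)
  expect_true(all(ut$truth$cls == "neither"))
  hits <- scan_utr(ut$utrs, c(cfg$words$cs, cfg$words$is))
  expect_equal(nrow(hits), 0L)
})

test_that("planted class counts match the configuration", {
  cfg <- tiny_config(seed = 84)
  ut <- gen_utrs(cfg)
  tab <- table(ut$truth$cls)
  expect_equal(unname(tab[["CS_only"]]), round(cfg$f_cs * cfg$n_genes))
  expect_equal(unname(tab[["IS_only"]]), round(cfg$f_is * cfg$n_genes))
  expect_equal(unname(tab[["both"]]), round(cfg$f_both * cfg$n_genes))
  # truth/FASTA consistency: the self-test re-scan in sim_all passes
  expect_silent(sim_all(cfg, dir = NULL, verify = TRUE))
  # planted positions hold the planted words
  w <- cfg$words$is[["IS"]]
  is_rows <- ut$truth[ut$truth$cls == "IS_only", ]
  for (i in seq_len(min(10, nrow(is_rows))))
    expect_equal(substr(ut$utrs[[is_rows$gene_id[i]]],
                        is_rows$is_pos[i] + 1,
                        is_rows$is_pos[i] + nchar(w)), w)
})

test_that("background word frequency is near the i.i.d. expectation", {
  cfg <- tiny_config(seed = 85, n_genes = 400L, f_cs = 0, f_is = 0,
                     f_both = 0, gc = 0.5, utr_len_min = 500L,
                     utr_len_meanlog = 6.3)
  ut <- gen_utrs(cfg)
  # count a fixed 6-mer unrelated to the guide over ~1e6 per-position
  # trials; at GC 0.5 every 6-mer has probability 4^-6
  word <- "ACGTCA"
  n_pos <- sum(ut$truth$length - nchar(word) + 1)
  hits <- nrow(scan_utr(ut$utrs, word))
  p0 <- 0.25^6
  expect_lt(abs(hits - n_pos * p0), 4 * sqrt(n_pos * p0))
})

test_that("expression effects are additive by class", {
  cfg <- sim_config(n_genes = 2000, master_seed = 86,
                    utr_len_meanlog = 5.8, utr_len_sdlog = 0.3,
                    interaction = 0)
  ut <- gen_utrs(cfg)
  ex <- gen_expression(ut$truth, cfg)
  lfc <- rowMeans(ex$mat[, ex$group_labels == "treatment"]) -
    rowMeans(ex$mat[, ex$group_labels == "control"])
  for (cl in c("CS_only", "IS_only", "both", "neither")) {
    idx <- ut$truth$cls == cl
    expected <- unique(ut$truth$expected_lfc[idx])
    se <- cfg$sigma * sqrt(2 / cfg$replicates) / sqrt(sum(idx))
    expect_lt(abs(mean(lfc[idx]) - expected), 4 * se)
  }
  # null configuration: down-set rate compatible with the t threshold
  cfg0 <- sim_config(n_genes = 2000, master_seed = 87, f_cs = 0,
                     f_is = 0, f_both = 0, utr_len_meanlog = 5.8)
  ut0 <- gen_utrs(cfg0)
  ex0 <- gen_expression(ut0$truth, cfg0)
  rec0 <- per_gene_stats(ex0$mat, ex0$group_labels)
  p_fp <- pt(-4, df = 2 * cfg0$replicates - 2)
  expect_lt(length(stratify_by_t(rec0)$down),
            2000 * p_fp + 4 * sqrt(2000 * p_fp) + 3)
})

test_that("clip libraries have the configured structure", {
  cfg <- tiny_config(seed = 88)
  ut <- gen_utrs(cfg)
  clip <- gen_clip_reads(ut$truth, cfg)
  n_sites <- nrow(clip$true_sites)
  expect_equal(n_sites,
               sum(ut$truth$cls %in% c("CS_only", "IS_only")) +
                 2 * sum(ut$truth$cls == "both"))
  # treatment read total ~ sites * peak_reads + background
  exp_bg <- cfg$clip_background_rate * sum(ut$truth$length)
  exp_treat <- n_sites * cfg$clip_peak_reads + exp_bg
  expect_lt(abs(length(clip$treat) - exp_treat), 4 * sqrt(exp_treat))
  expect_lt(abs(length(clip$ctrl) - exp_bg), 4 * sqrt(exp_bg) + 3)
})

test_that("qPCR construction is invertible and carries the planted rho", {
  cfg <- tiny_config(seed = 89, qpcr_cq_noise = 0)
  qp <- gen_qpcr(cfg)
  cn <- cnrq(qp$cq, qp$reference_genes)
  # noiseless Cq: CNRQ recovers the latent quantities up to per-gene scale
  lat <- 2^qp$truth$log2_quantity[, "target"]
  ratio <- cn$cnrq[, "target"] / lat
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  # planted rank correlation is recovered over repeated panels
  rhos <- vapply(1:60, function(i) {
    qpi <- gen_qpcr(tiny_config(seed = 1000 + i))
    cni <- cnrq(qpi$cq, qpi$reference_genes)
    spearman(cni$cnrq[, "mirna"], cni$cnrq[, "target"])$rho
  }, 0)
  expect_lt(abs(mean(rhos) - (-0.5)), 2 * sd(rhos) / sqrt(60))
})

test_that("emitted files are plain text and re-readable", {
  cfg <- tiny_config(seed = 90)
  dir <- file.path(tempdir(), "simout")
  sim <- sim_all(cfg, dir = dir)
  expect_true(all(file.exists(unlist(sim$files))))
  utrs <- read_fasta(sim$files$utrs, "DNA")
  expect_identical(utrs, sim$utrs)
  mir <- read_fasta(sim$files$mirna, "RNA")
  expect_equal(mir[[1]]$sequence, cfg$mirna$sequence)
  reads <- read_bed_reads(sim$files$clip_treat)
  expect_equal(length(reads), length(sim$clip$treat))
  truth <- jsonlite::read_json(sim$files$truth, simplifyVector = TRUE)
  expect_equal(truth$truth$cls, sim$truth$cls)
  unlink(dir, recursive = TRUE)
})
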