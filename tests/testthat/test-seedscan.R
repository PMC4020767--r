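test_that("target words are the reverse complement of the seed window", {
  mir <- mature_mirna("m", "AACCGGUUAACCGGUUAACCGGUUA")
  tw <- derive_target_word(mir, seed_definition("IS", 6, 7))
  expect_equal(tw$word, "GGTTAAC")  # window 6-12 is GUUAACC

  # the published guide: the internal seed 6-12 yields the printed word
  expect_equal(derive_target_word(mir4728_3p(),
                                  seed_definition("IS", 6, 7))$word,
               "GAGGTCA")
  expect_equal(derive_target_word(mir4728_3p(),
                                  seed_definition("CS", 2, 7))$word,
               "TCAGCAT")

  # anchor+shift window identity: anchor 2 shift 1 == anchor 3 shift 0
  w1 <- derive_target_word(mir, seed_definition("a", 2, 7, isomir_shift = 1))
  w2 <- derive_target_word(mir, seed_definition("b", 3, 7))
  expect_equal(w1$word, w2$word)

  expect_error(derive_target_word(mir, seed_definition("x", 22, 7)),
               "exceeds")
})

test_that("shifted variants move the window toward the 3' end", {
  cs <- seed_definition("CS", 2, 7)
  v <- shifted_variants(cs, 1)
  expect_named(v, c("CS", "CS+1"))
  expect_equal(bimodalseed:::seed_window(v$CS), c(2, 8))
  expect_equal(bimodalseed:::seed_window(v$`CS+1`), c(3, 9))
  expect_length(shifted_variants(cs, 0), 1)
  v2 <- shifted_variants(seed_definition("IS", 6, 6), 2)
  expect_equal(lapply(v2, bimodalseed:::seed_window),
               list(IS = c(6, 11), `IS+1` = c(7, 12), `IS+2` = c(8, 13)),
               ignore_attr = TRUE)
})

test_that("scan_utr finds exact overlapping matches with 0-based starts", {
  hits <- scan_utr("TTGAGGTCATT", "GAGGTCA", gene_id = "g1")
  expect_equal(hits$start, 2L)
  expect_equal(hits$gene_id, "g1")

  # the mutant word is not a match for the wild-type word and vice versa
  expect_equal(nrow(scan_utr("AACTCCAGTAA", "GAGGTCA", gene_id = "g")), 0L)
  expect_equal(scan_utr("AACTCCAGTAA", "CTCCAGT", gene_id = "g")$start, 2L)

  expect_equal(scan_utr("AAAAAA", "AAAA", gene_id = "g")$start, c(0L, 1L, 2L))
  expect_equal(nrow(scan_utr("", "AAAA", gene_id = "g")), 0L)
  expect_equal(nrow(scan_utr("GANGTCA", "GAGGTCA", gene_id = "g")), 0L)
})

test_that("scan_utr agrees with the naive oracle on random inputs", {
  set.seed(101)
  for (i in 1:200) {
    u <- random_utr(sample(20:300, 1), with_n = TRUE)
    w <- random_word(sample(5:9, 1))
    expect_equal(scan_utr(u, w, gene_id = "g")$start, naive_scan(u, w),
                 info = paste(u, w))
  }
})

test_that("a planted word is always recovered at its position", {
  set.seed(102)
  mir <- mature_mirna("m", paste(sample(c("A", "C", "G", "U"), 22, TRUE),
                                 collapse = ""))
  for (i in 1:50) {
    sd <- seed_definition("s", sample(1:10, 1), sample(5:9, 1))
    w <- derive_target_word(mir, sd)$word
    len <- sample(50:150, 1)
    pos <- sample(0:(len - nchar(w)), 1)
    u <- random_utr(len)
    substr(u, pos + 1, pos + nchar(w)) <- w
    expect_true(pos %in% scan_utr(u, w, gene_id = "g")$start)
  }
})

test_that("classify_genes yields an exclusive, exhaustive partition", {
  utrs <- c(g1 = "AAGAGGTCAAA",        # IS word only
            g2 = "TTTCAGCATTT",        # CS word only
            g3 = "GAGGTCATTTCAGCAT",   # both
            g4 = "ACGTACGTACGT",       # neither
            g5 = "")                   # empty -> neither
  ann <- classify_genes(utrs, cs_words = "TCAGCAT", is_words = "GAGGTCA")
  expect_equal(as.character(ann$cls),
               c("IS_only", "CS_only", "both", "neither", "neither"))
  expect_equal(ann$n_cs, c(0L, 1L, 1L, 0L, 0L))
  expect_equal(ann$n_is, c(1L, 0L, 1L, 0L, 0L))
  # partition property on random sequences
  set.seed(103)
  ru <- setNames(vapply(1:80, function(i) random_utr(200), ""),
                 sprintf("r%02d", 1:80))
  ann2 <- classify_genes(ru, c("TCAGCAT", "CAGCATC"), c("GAGGTCA", "AGGTCAG"))
  expect_false(anyNA(ann2$cls))
  expect_equal(nrow(ann2), 80L)
  with(ann2, {
    expect_true(all((cls == "both") == (n_cs >= 1 & n_is >= 1)))
    expect_true(all((cls == "neither") == (n_cs == 0 & n_is == 0)))
  })
  expect_error(classify_genes(utrs, "GAGGTCA", "GAGGTCA"), "overlap")
  expect_error(classify_genes(c(g1 = "ACGT", g1 = "ACGT"),
                              "TCAGCAT", "GAGGTCA"), "duplicate")
})

test_that("extract_context builds a sensible position frequency matrix", {
  pfm0 <- extract_context(c(g = "TTGAGGTCATT"), "GAGGTCA", flank = 0)
  expect_equal(pfm0$n_fragments, 1L)
  expect_equal(unname(pfm0$pfm["G", 1]), 1)       # one-hot word columns
  expect_equal(unname(colSums(pfm0$pfm)), rep(1, 7))

  # identical fragments: every column has a single 1
  utrs <- setNames(rep("CCCGAGGTCACCC", 5), paste0("g", 1:5))
  pfmI <- extract_context(utrs, "GAGGTCA", flank = 3)
  expect_true(all(apply(pfmI$pfm, 2, max) == 1))

  # no matches
  pfmE <- extract_context(c(g = "AAAA"), "GAGGTCA")
  expect_equal(pfmE$n_fragments, 0L)

  # random flanks: word columns one-hot, flank columns near background
  set.seed(104)
  frag <- vapply(1:300, function(i) {
    u <- random_utr(27)
    substr(u, 11, 17) <- "GAGGTCA"
    u
  }, "")
  pfmR <- extract_context(setNames(frag, paste0("f", 1:300)), "GAGGTCA",
                          flank = 10)
  expect_equal(pfmR$n_fragments, 300L)
  expect_true(all(apply(pfmR$pfm[, 11:17], 2, max) == 1))
  expect_true(all(abs(pfmR$pfm[, c(1:10, 18:27)] - 0.25) < 0.12))

  # edge truncation: fragment at UTR start still gives unit columns
  pfmT <- extract_context(c(g = "GAGGTCATT"), "GAGGTCA", flank = 5)
  expect_equal(unname(colSums(pfmT$counts)[1:5]), rep(0L, 5))
  expect_equal(unname(colSums(pfmT$pfm[, 6:12])), rep(1, 7))
})
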