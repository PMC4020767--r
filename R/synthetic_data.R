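#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator with the
#' default study-like conditions: 5000 genes with log-normal UTR lengths,
#' 10% canonical-seed-only and 10% internal-seed-only genes plus 5%
#' carrying both, additive repression of -0.25 (CS) and -0.4 (IS) log2
#' units with Gaussian noise sd 0.3 over 6 replicates per group, CLIP
#' piles of ~30 reads on true sites in the treatment library only, a
#' 0.6/0.3/0.1 multinomial over 5' isomiR offsets 0/1/2, and a qPCR panel
#' of 19 samples with planted Spearman correlation -0.5 between the miRNA
#' and its target.  Every stream derives its own RNG seed from
#' `master_seed`, so identical configurations reproduce byte-identical
#' outputs.
#'
#' @param n_genes Number of genes.
#' @param utr_len_meanlog,utr_len_sdlog,utr_len_min,utr_len_max Log-normal
#'   UTR length distribution and clipping bounds (nt).
#' @param gc GC content of background sequence.
#' @param f_cs,f_is,f_both Fractions of genes with only CS, only IS, or
#'   both site types (must sum to <= 1).
#' @param delta_cs,delta_is Planted log2 fold changes (<= 0).
#' @param interaction Extra log2 effect added to `both` genes on top of
#'   `delta_cs + delta_is`.
#' @param sigma Replicate noise sd (log2 units).
#' @param replicates Samples per group.
#' @param mirna_id,mirna_seq The synthetic guide (RNA, 5'->3').
#' @param seed_length Word size for the planted seeds.
#' @param max_shift isomiR shifts included in the scan word set.
#' @param extended_fraction Fraction of IS-only genes whose planted site
#'   is a perfect 12-nt complement extending the internal seed (for the
#'   duplex long-run screen).
#' @param extended_length Length of the extended complement.
#' @param clip_peak_reads Mean treatment reads per true site.
#' @param clip_background_rate Background reads per nucleotide (both
#'   libraries).
#' @param clip_read_len,clip_jitter CLIP read length and 5' jitter (nt).
#' @param isomir_props Named vector of 5'-offset proportions (names are
#'   offsets; must sum to 1).
#' @param isomir_n_reads Reads at the miRNA locus.
#' @param isomir_total_mapped Total genome-mapped reads (normalisation
#'   denominator).
#' @param qpcr_n_samples Tumour panel size.
#' @param qpcr_rho Planted Spearman correlation between miRNA and target
#'   quantities (|rho| < 1).
#' @param qpcr_sd_log2 sd of the latent log2 quantities.
#' @param qpcr_cq_noise Cq measurement noise sd (cycles).
#' @param master_seed Master RNG seed.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 5000L,
                       utr_len_meanlog = 6.35, utr_len_sdlog = 0.6,
                       utr_len_min = 100L, utr_len_max = 3000L,
                       gc = 0.45,
                       f_cs = 0.10, f_is = 0.10, f_both = 0.05,
                       delta_cs = -0.25, delta_is = -0.40,
                       interaction = 0,
                       sigma = 0.3, replicates = 6L,
                       mirna_id = "syn-miR-1",
                       mirna_seq = "UAGAAUCUUGCACUCGGCCUUUCCA",
                       seed_length = 7L, max_shift = 1L,
                       extended_fraction = 0,
                       extended_length = 12L,
                       clip_peak_reads = 30, clip_background_rate = 0.005,
                       clip_read_len = 30L, clip_jitter = 5L,
                       isomir_props = c("0" = 0.6, "1" = 0.3, "2" = 0.1),
                       isomir_n_reads = 5000L,
                       isomir_total_mapped = 1e6,
                       qpcr_n_samples = 19L, qpcr_rho = -0.5,
                       qpcr_sd_log2 = 1, qpcr_cq_noise = 0.1,
                       master_seed = 1L) {
  cfg <- as.list(environment())
  if (f_cs + f_is + f_both > 1)
    stop("site-class fractions must sum to <= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  if (delta_cs > 0 || delta_is > 0)
    stop("planted effects are repressive: delta_cs, delta_is <= 0")
  if (abs(sum(isomir_props) - 1) > 1e-9)
    stop("isomir_props must sum to 1")
  if (abs(qpcr_rho) >= 1) stop("|qpcr_rho| must be < 1")
  mir <- mature_mirna(mirna_id, mirna_seq)
  words <- sim_word_sets(mir, seed_length, max_shift)
  all_w <- c(words$cs, words$is)
  if (anyDuplicated(all_w))
    stop("guide yields colliding CS/IS word sets; choose another mirna_seq")
  cfg$mirna <- mir
  cfg$words <- words
  structure(cfg, class = "sim_config")
}

# CS and IS word sets including shifted variants, as named character
# vectors (names = seed names)
sim_word_sets <- function(mir, seed_length, max_shift) {
  cs <- shifted_variants(seed_definition("CS", 2L, seed_length), max_shift)
  is_ <- shifted_variants(seed_definition("IS", 6L, seed_length), max_shift)
  list(cs = vapply(cs, function(s) derive_target_word(mir, s)$word, ""),
       is = vapply(is_, function(s) derive_target_word(mir, s)$word, ""),
       cs_seeds = cs, is_seeds = is_)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_genes, " genes; f(CS,IS,both) = ",
      x$f_cs, "/", x$f_is, "/", x$f_both, "; delta(CS,IS) = ",
      x$delta_cs, "/", x$delta_is, "; sigma ", x$sigma, " x",
      x$replicates, " reps; master seed ", x$master_seed, "\n", sep = "")
  invisible(x)
}

# per-stream RNG seed derived from the master seed (kept under 2^31)
stream_seed <- function(master, stream) {
  (as.numeric(master) * 7919 +
     sum(utf8ToInt(stream)) * 104729) %% 2147483647
}

# bases a guide nucleotide cannot pair with (WC or GU), DNA alphabet
.BLOCKERS <- list(A = c("A", "C", "G"), C = c("A", "C", "T"),
                  G = c("A", "G"), U = c("C", "T"))

random_dna <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic UTR set with planted seed sites
#'
#' Draws i.i.d. background sequence at the configured GC content and
#' plants one site per selected class (one CS and one non-overlapping IS
#' site for `both` genes).  The two bases immediately flanking every
#' planted site are chosen to be unable to pair with the guide's
#' continuation, so a planted seed match never extends into a longer
#' complementary run by construction; extended 12-nt complements are
#' planted explicitly for the configured fraction of IS genes.  Any UTR
#' whose scan over the full (shift-inclusive) word set deviates from the
#' planted truth - a chance word occurrence, or a planted word recreated
#' by background - is resampled, so class labels are exact.
#'
#' @param config A [sim_config()].
#' @return List with `utrs` (named character vector) and `truth`
#'   (data.frame `gene_id`, `cls`, `length`, `cs_pos`, `is_pos`,
#'   `extended`, `expected_lfc`; positions 0-based starts).
#' @export
gen_utrs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$master_seed, "utrs"))
  n <- config$n_genes
  k <- config$seed_length
  ids <- sprintf("g%05d", seq_len(n))
  lens <- pmin(pmax(round(stats::rlnorm(n, config$utr_len_meanlog,
                                        config$utr_len_sdlog)),
                    config$utr_len_min), config$utr_len_max)
  min_needed <- 2L * (config$extended_length + 4L) + 4L
  if (any(lens < min_needed))
    lens <- pmax(lens, min_needed)
  n_cs <- round(config$f_cs * n); n_is <- round(config$f_is * n)
  n_both <- round(config$f_both * n)
  cls <- sample(rep(c("CS_only", "IS_only", "both", "neither"),
                    c(n_cs, n_is, n_both, n - n_cs - n_is - n_both)))
  n_ext <- round(config$extended_fraction * n_is)
  extended <- logical(n)
  if (n_ext > 0L)
    extended[sample(which(cls == "IS_only"), n_ext)] <- TRUE

  cs_word <- config$words$cs[["CS"]]
  is_word <- config$words$is[["IS"]]
  mir_chars <- strsplit(config$mirna$sequence, "")[[1]]
  # extended complement: guide window starting at the IS anchor and
  # running 3'-ward, so it contains the IS but never the CS window
  ext_win <- c(6L, 6L + config$extended_length - 1L)
  if (ext_win[2] > length(mir_chars))
    stop("extended complement exceeds the guide 3' end")
  ext_word <- chartr("U", "T", as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(substr(config$mirna$sequence,
                                 ext_win[1], ext_win[2])))))
  ext_is_off <- regexpr(is_word, ext_word, fixed = TRUE)[1] - 1L
  if (ext_is_off < 0L)
    stop("internal inconsistency: IS word not inside extended complement")
  all_words <- unique(c(config$words$cs, config$words$is))

  # blocker base for the UTR position 5' of a planted word (pairs with
  # guide position win_end + 1) and 3' of it (pairs with win_start - 1)
  blocker <- function(mir_pos) {
    if (mir_pos < 1L || mir_pos > length(mir_chars)) return(NULL)
    sample(.BLOCKERS[[mir_chars[mir_pos]]], 1L)
  }
  plant <- function(seqc, start0, word, win) {
    # start0 0-based; win = guide window (start, end) the word complements
    idx <- start0 + seq_len(nchar(word))
    seqc[idx] <- strsplit(word, "")[[1]]
    b5 <- blocker(win[2] + 1L)
    if (!is.null(b5)) seqc[start0] <- b5
    b3 <- blocker(win[1] - 1L)
    if (!is.null(b3)) seqc[start0 + nchar(word) + 1L] <- b3
    seqc
  }

  cs_win <- c(2L, 2L + k - 1L); is_win <- c(6L, 6L + k - 1L)
  utrs <- character(n)
  cs_pos <- rep(NA_integer_, n); is_pos <- rep(NA_integer_, n)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) && tries < 60L) {
    tries <- tries + 1L
    for (g in todo) {
      len <- lens[g]
      seqc <- random_dna(len, config$gc)
      # positions leave room for the two blocker bases
      if (cls[g] == "CS_only") {
        p <- sample(seq.int(1L, len - k - 1L), 1L)
        seqc <- plant(seqc, p, cs_word, cs_win)
        cs_pos[g] <- p
      } else if (cls[g] == "IS_only") {
        w <- if (extended[g]) ext_word else is_word
        win <- if (extended[g]) ext_win else is_win
        p <- sample(seq.int(1L, len - nchar(w) - 1L), 1L)
        seqc <- plant(seqc, p, w, win)
        is_pos[g] <- if (extended[g]) p + ext_is_off else p
      } else if (cls[g] == "both") {
        repeat {
          p1 <- sample(seq.int(1L, len - k - 1L), 1L)
          p2 <- sample(seq.int(1L, len - k - 1L), 1L)
          if (abs(p1 - p2) > k + 2L) break
        }
        seqc <- plant(seqc, p1, cs_word, cs_win)
        seqc <- plant(seqc, p2, is_word, is_win)
        cs_pos[g] <- p1; is_pos[g] <- p2
      }
      utrs[g] <- paste(seqc, collapse = "")
    }
    # verify: scan must reproduce exactly the planted occurrences
    found <- scan_utr(setNames(utrs[todo], ids[todo]), all_words)
    ok <- vapply(seq_along(todo), function(ii) {
      g <- todo[ii]
      f <- found[found$gene_id == ids[g], , drop = FALSE]
      expected_sites(cls[g], extended[g], cs_pos[g], is_pos[g],
                     cs_word, is_word, ext_word, utrs[g], all_words, f)
    }, TRUE)
    todo <- todo[!ok]
  }
  if (length(todo))
    stop("could not generate clean UTRs for ", length(todo),
         " genes after 60 rounds; word frequency infeasible for UTR length")
  lfc <- ifelse(cls == "CS_only", config$delta_cs,
         ifelse(cls == "IS_only", config$delta_is,
         ifelse(cls == "both",
                config$delta_cs + config$delta_is + config$interaction, 0)))
  list(utrs = setNames(utrs, ids),
       truth = data.frame(gene_id = ids, cls = cls, length = lens,
                          cs_pos = cs_pos, is_pos = is_pos,
                          extended = extended, expected_lfc = lfc,
                          stringsAsFactors = FALSE))
}

# check that the scan hits of one gene are exactly the planted ones
expected_sites <- function(cls, extended, cs_pos, is_pos, cs_word,
                           is_word, ext_word, utr, all_words, found) {
  if (cls == "neither") return(nrow(found) == 0L)
  if (cls == "CS_only")
    return(nrow(found) == 1L && found$word == cs_word &&
             found$start == cs_pos)
  if (cls == "both") {
    if (nrow(found) != 2L) return(FALSE)
    f <- found[order(found$word), ]
    e <- data.frame(word = c(cs_word, is_word), start = c(cs_pos, is_pos))
    e <- e[order(e$word), ]
    return(all(f$word == e$word) && all(f$start == e$start))
  }
  # IS_only: plain site -> exactly the IS word at is_pos; extended site ->
  # every hit must be a sub-word of the planted complement at its
  # construction-implied offset
  if (!extended)
    return(nrow(found) == 1L && found$word == is_word &&
             found$start == is_pos)
  if (!nrow(found)) return(FALSE)
  ins0 <- regexpr(is_word, ext_word, fixed = TRUE)[1] - 1L
  p12 <- is_pos - ins0
  inside <- found$start >= p12 &
    found$start + nchar(found$word) <= p12 + nchar(ext_word)
  if (!all(inside)) return(FALSE)
  ref <- scan_utr(ext_word, all_words, gene_id = "ins")
  if (!nrow(ref)) return(FALSE)
  setequal(paste(found$word, found$start - p12), paste(ref$word, ref$start))
}

#' Generate replicate expression matrices from planted effects
#'
#' Control replicates are Normal(0, sigma); treatment replicates are
#' Normal(expected log2 fold change, sigma), the additive class effect
#' recorded in the truth table.
#'
#' @param truth Truth data.frame from [gen_utrs()].
#' @param config A [sim_config()].
#' @return List with `mat` (genes x samples log2 matrix),
#'   `group_labels`.
#' @export
gen_expression <- function(truth, config) {
  set.seed(stream_seed(config$master_seed, "expression"))
  n <- nrow(truth); r <- config$replicates
  ctrl <- matrix(rnorm(n * r, 0, config$sigma), n, r)
  trt <- matrix(rnorm(n * r, rep(truth$expected_lfc, r), config$sigma),
                n, r)
  mat <- cbind(ctrl, trt)
  rownames(mat) <- truth$gene_id
  colnames(mat) <- c(paste0("ctrl_", seq_len(r)),
                     paste0("treat_", seq_len(r)))
  list(mat = mat,
       group_labels = rep(c("control", "treatment"), each = r))
}

#' Generate CLIP read libraries with treatment-only site piles
#'
#' Both libraries get uniform background reads at
#' `clip_background_rate` per nucleotide; the treatment library
#' additionally piles Poisson(`clip_peak_reads`) reads on every planted
#' site, with 5' starts jittered +/- `clip_jitter` nt around the position
#' that centres the read on the site.
#'
#' @param truth Truth data.frame from [gen_utrs()].
#' @param config A [sim_config()].
#' @return List with `treat`, `ctrl` (`GRanges`, transcript space,
#'   `count = 1` per read) and `true_sites` (data.frame `gene_id`,
#'   `seed_type`, `start`, `end`, 0-based half-open site intervals).
#' @export
gen_clip_reads <- function(truth, config) {
  set.seed(stream_seed(config$master_seed, "clip"))
  k <- config$seed_length
  rl <- config$clip_read_len
  sites <- rbind(
    data.frame(gene_id = truth$gene_id, seed_type = "CS",
               start = truth$cs_pos, len = truth$length,
               stringsAsFactors = FALSE),
    data.frame(gene_id = truth$gene_id, seed_type = "IS",
               start = truth$is_pos, len = truth$length,
               stringsAsFactors = FALSE))
  sites <- sites[!is.na(sites$start), , drop = FALSE]
  sites$end <- sites$start + k
  mk_reads <- function(gene, starts, len) {
    starts <- pmin(pmax(starts, 0L), pmax(len - rl, 0L))
    GenomicRanges::GRanges(gene,
                           IRanges::IRanges(starts + 1L,
                                            width = pmin(rl, len)),
                           strand = "+", count = 1L)
  }
  # treatment piles: draw all per-site read counts at once, then expand
  nr <- rpois(nrow(sites), config$clip_peak_reads)
  gene_p <- rep(sites$gene_id, nr)
  len_p <- rep(sites$len, nr)
  centre <- rep(sites$start + k %/% 2L - rl %/% 2L, nr)
  starts_p <- centre + sample(seq.int(-config$clip_jitter,
                                      config$clip_jitter),
                              sum(nr), replace = TRUE)
  background <- function() {
    nb <- rpois(nrow(truth), config$clip_background_rate * truth$length)
    gene <- rep(truth$gene_id, nb)
    len <- rep(truth$length, nb)
    starts <- as.integer(floor(runif(length(gene), 0, pmax(len - rl, 1))))
    list(gene = gene, starts = starts, len = len)
  }
  bg_t <- background()
  bg_c <- background()
  treat <- mk_reads(c(gene_p, bg_t$gene), c(starts_p, bg_t$starts),
                    c(len_p, bg_t$len))
  ctrl <- mk_reads(bg_c$gene, bg_c$starts, bg_c$len)
  list(treat = treat, ctrl = ctrl,
       true_sites = sites[, c("gene_id", "seed_type", "start", "end")])
}

#' Generate small-RNA reads with a multinomial 5'-offset spectrum
#'
#' Reads at a synthetic miRNA locus whose 5' starts follow the configured
#' offset proportions (positive = truncated); every read keeps the
#' canonical 3' end.
#'
#' @param config A [sim_config()].
#' @return List with `reads` (`GRanges`), `locus` (`GRanges`, the
#'   canonical mature interval), `proportions` (the truth).
#' @export
gen_isomir_reads <- function(config) {
  set.seed(stream_seed(config$master_seed, "isomir"))
  offs <- as.integer(names(config$isomir_props))
  locus_start <- 1001L
  mature_len <- nchar(config$mirna$sequence)
  draw <- sample(offs, config$isomir_n_reads, replace = TRUE,
                 prob = config$isomir_props)
  reads <- GenomicRanges::GRanges(
    "mirchr",
    IRanges::IRanges(locus_start + draw,
                     locus_start + mature_len - 1L),
    strand = "+", count = 1L)
  locus <- GenomicRanges::GRanges(
    "mirchr", IRanges::IRanges(locus_start, locus_start + mature_len - 1L),
    strand = "+")
  list(reads = reads, locus = locus, proportions = config$isomir_props)
}

#' Generate a qPCR Cq table with a planted rank correlation
#'
#' Latent log2 quantities of the miRNA and its target are drawn from a
#' Gaussian copula whose Pearson parameter `2 sin(pi rho / 6)` yields the
#' configured Spearman correlation; reference genes are constant up to
#' noise.  `Cq = baseline - log2(quantity) + Normal(0, cq_noise)`, so
#' [cnrq()] at efficiency 2 inverts the construction up to per-gene scale.
#'
#' @param config A [sim_config()].
#' @return List with `cq` (samples x genes matrix; genes `mirna`,
#'   `target`, `ref1..ref3`), `truth` (latent log2 quantities and the
#'   planted rho), `reference_genes`.
#' @export
gen_qpcr <- function(config) {
  set.seed(stream_seed(config$master_seed, "qpcr"))
  n <- config$qpcr_n_samples
  r_pearson <- 2 * sin(pi * config$qpcr_rho / 6)
  z1 <- rnorm(n)
  z2 <- r_pearson * z1 + sqrt(1 - r_pearson^2) * rnorm(n)
  q <- cbind(mirna = config$qpcr_sd_log2 * z1,
             target = config$qpcr_sd_log2 * z2,
             ref1 = 0, ref2 = 0, ref3 = 0)
  baselines <- c(mirna = 25, target = 28, ref1 = 20, ref2 = 21, ref3 = 22)
  cq <- sweep(-q, 2L, baselines, `+`) +
    matrix(rnorm(length(q), 0, config$qpcr_cq_noise), nrow(q), ncol(q))
  rownames(cq) <- sprintf("S%02d", seq_len(n))
  list(cq = cq,
       truth = list(log2_quantity = q, rho_spearman = config$qpcr_rho),
       reference_genes = c("ref1", "ref2", "ref3"))
}

#' Generate every pipeline input, with ground truth
#'
#' Runs all generator streams and, when `dir` is given, writes the
#' standard file formats: `utrs.fa`, `mirna.fa`, `expression.tsv`,
#' `clip_treat.bed` / `clip_ctrl.bed`, `isomir_reads.bed`, `cq.tsv` and a
#' `truth.json` manifest.  With `verify = TRUE` (default) the emitted
#' UTRs are re-scanned and checked against the truth table.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param verify Re-scan emitted UTRs against the truth.
#' @return List with `utrs`, `truth`, `expression`, `clip`, `isomir`,
#'   `qpcr`, `config`, and `files` when written.
#' @export
sim_all <- function(config = sim_config(), dir = NULL, verify = TRUE) {
  ut <- gen_utrs(config)
  expr <- gen_expression(ut$truth, config)
  clip <- gen_clip_reads(ut$truth, config)
  iso <- gen_isomir_reads(config)
  qp <- gen_qpcr(config)
  if (verify) {
    ann <- classify_genes(ut$utrs, config$words$cs, config$words$is)
    if (!all(as.character(ann$cls) == ut$truth$cls))
      stop("generator self-check failed: re-scan disagrees with truth")
  }
  out <- list(utrs = ut$utrs, truth = ut$truth, expression = expr,
              clip = clip, isomir = iso, qpcr = qp, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- list(
      utrs = file.path(dir, "utrs.fa"),
      mirna = file.path(dir, "mirna.fa"),
      expression = file.path(dir, "expression.tsv"),
      clip_treat = file.path(dir, "clip_treat.bed"),
      clip_ctrl = file.path(dir, "clip_ctrl.bed"),
      isomir = file.path(dir, "isomir_reads.bed"),
      cq = file.path(dir, "cq.tsv"),
      truth = file.path(dir, "truth.json"))
    write_fasta(ut$utrs, f$utrs)
    write_fasta(setNames(config$mirna$sequence, config$mirna$id), f$mirna)
    write.table(data.frame(gene_id = rownames(expr$mat), expr$mat,
                           check.names = FALSE),
                f$expression, sep = "\t", quote = FALSE, row.names = FALSE)
    write_reads_bed(clip$treat, f$clip_treat)
    write_reads_bed(clip$ctrl, f$clip_ctrl)
    write_reads_bed(iso$reads, f$isomir)
    write.table(data.frame(sample = rownames(qp$cq), qp$cq,
                           check.names = FALSE),
                f$cq, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(truth = ut$truth,
           clip_sites = clip$true_sites,
           isomir_proportions = as.list(iso$proportions),
           qpcr_rho = config$qpcr_rho,
           group_labels = expr$group_labels,
           words = config$words[c("cs", "is")]),
      f$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$files <- f
  }
  out
}

# BED6 writer with deterministic formatting (reads carry count as score)
write_reads_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = sprintf("read_%06d", seq_len(length(gr))),
    score = S4Vectors::mcols(gr)$count %||% rep(1L, length(gr)),
    strand = as.character(GenomicRanges::strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
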