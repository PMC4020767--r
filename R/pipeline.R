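#' Run the full internal-seed analysis end to end
#'
#' Executes the analysis graph on synthetic data (or user files written in
#' the same layout): isomiR profiling selects the active seed shifts, the
#' shifted CS/IS word sets are scanned over the UTRs, per-gene statistics
#' rank the genes, the word-enrichment landscape and the seed-class ECDF
#' comparison are computed, internal-seed sites are screened with the
#' duplex model, CLIP peaks are called against the control library, and
#' the qPCR panel is CNRQ-normalised and correlated.  All stage outputs
#' plus a JSON run manifest are written under `out_dir`; outputs contain
#' no timestamps, so a rerun with the same configuration and seed is
#' byte-identical.
#'
#' @param config A [sim_config()] describing the synthetic inputs.
#' @param out_dir Output directory.
#' @param k Word size used for the enrichment landscape (default
#'   `config$seed_length`).
#' @param force Rerun even when a manifest with the same configuration
#'   hash already exists.
#' @param quiet Suppress per-stage progress messages.
#' @return The run manifest (invisibly): list with `config_hash`,
#'   `master_seed`, `stages` (named input/output paths), `results`
#'   (headline numbers).
#' @export
run_all <- function(config = sim_config(), out_dir, k = NULL,
                    force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  k <- k %||% config$seed_length
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[run_all] ", ...)
  cfg_plain <- unclass(config)
  cfg_plain$mirna <- unclass(cfg_plain$mirna)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  config_hash <- as.character(tools::md5sum(
    local({ tf <- file.path(out_dir, "config.json")
            writeLines(cfg_json, tf); tf })))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, unname(config_hash)) &&
        all(file.exists(file.path(out_dir, unlist(old$stages))))) {
      say("outputs up to date (config hash ", substr(config_hash, 1, 8),
          "); use force = TRUE to rerun")
      return(invisible(old))
    }
  }
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) say(name, " (",
                              round(proc.time()[["elapsed"]] - t0, 1),
                              "s elapsed)")
  stages <- list()

  stage("simulate")
  sim <- sim_all(config, dir = file.path(out_dir, "inputs"))
  stages$inputs <- unlist(sim$files, use.names = FALSE)

  stage("isomir")
  prof <- five_prime_offsets(sim$isomir$reads, sim$isomir$locus,
                             total_mapped = config$isomir_total_mapped)
  shifts <- active_seed_shifts(prof, min_fraction = 0.15)
  stages$isomir <- file.path(out_dir, "isomir_profile.tsv")
  write_isomir_profile(prof, stages$isomir)

  stage("scan")
  max_shift <- max(c(0L, shifts))
  words <- sim_word_sets(config$mirna, config$seed_length, max_shift)
  matches <- scan_utr(sim$utrs, c(words$cs, words$is))
  stages$scan <- file.path(out_dir, "seed_matches.tsv")
  write.table(matches, stages$scan, sep = "\t", quote = FALSE,
              row.names = FALSE)

  stage("destats")
  rec <- per_gene_stats(sim$expression$mat, sim$expression$group_labels)
  ranked <- rank_by_downregulation(rec)
  stages$destats <- file.path(out_dir, "destats.tsv")
  write.table(rec, stages$destats, sep = "\t", quote = FALSE,
              row.names = FALSE)

  stage("enrich")
  idx <- build_word_index(sim$utrs, k)
  is_word <- words$is[["IS"]]
  cs_word <- words$cs[["CS"]]
  tw <- top_words(ranked, idx)
  lands <- lapply(unique(c(cs_word, is_word,
                           unlist(words$cs), unlist(words$is))),
                  function(w) landscape(ranked, idx, w))
  stages$enrich <- file.path(out_dir, "landscapes.tsv")
  write_landscapes(lands, stages$enrich)
  stages$top_words <- file.path(out_dir, "top_words.tsv")
  write.table(head(tw, 50L), stages$top_words, sep = "\t",
              quote = FALSE, row.names = FALSE)

  stage("ecdf")
  ann <- classify_genes(sim$utrs, words$cs, words$is)
  dist4 <- build_class_distributions(rec, ann)
  gap <- additivity_gap(dist4$CS_only$values, dist4$IS_only$values,
                        dist4$both$values, dist4$neither$values,
                        seed = config$master_seed)
  ecdf_tab <- do.call(rbind, lapply(dist4, function(d)
    data.frame(cls = d$cls, log2fc = d$values)))
  stages$ecdf <- file.path(out_dir, "class_log2fc.tsv")
  write.table(ecdf_tab, stages$ecdf, sep = "\t", quote = FALSE,
              row.names = FALSE)

  stage("duplex")
  strat <- stratify_by_t(rec)
  is_matches <- matches[matches$seed_name == "IS", , drop = FALSE]
  is_genes <- unique(is_matches$gene_id)
  screen <- screen_targets(config$mirna, sim$utrs, is_matches,
                           seed_definition("IS", 6L, config$seed_length),
                           down_set = intersect(strat$down, is_genes),
                           unaffected_set = intersect(strat$unaffected,
                                                      is_genes))
  stages$duplex <- file.path(out_dir, "duplex_screen.tsv")
  write.table(rbind(cbind(group = "down", screen$down),
                    cbind(group = "unaffected", screen$unaffected)),
              stages$duplex, sep = "\t", quote = FALSE, row.names = FALSE)

  stage("clip")
  lens <- setNames(sim$truth$length, sim$truth$gene_id)
  wins <- seed_windows(matches, lens)
  peaks <- call_peaks(wins, sim$clip$treat, sim$clip$ctrl)
  model <- data.frame(gene_id = sim$truth$gene_id, region = "UTR3",
                      start = 0L, end = sim$truth$length)
  peaks <- annotate_region(peaks, model)
  ov <- overlap_with_expression(peaks, strat$down)
  stages$clip <- file.path(out_dir, "clip_peaks.bed")
  write_peaks_bed(peaks, stages$clip)

  stage("correlate")
  cn <- cnrq(sim$qpcr$cq, sim$qpcr$reference_genes)
  sp <- spearman(cn$cnrq[, "mirna"], cn$cnrq[, "target"])
  stages$cnrq <- file.path(out_dir, "cnrq.tsv")
  write.table(data.frame(sample = rownames(cn$cnrq), cn$cnrq,
                         check.names = FALSE),
              stages$cnrq, sep = "\t", quote = FALSE, row.names = FALSE)

  # manifest records paths relative to out_dir so identical runs into
  # different directories produce identical files
  rel <- function(p) sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])",
                                          "\\\\\\1", out_dir), "/?"),
                         "", p)
  manifest <- list(
    config_hash = unname(config_hash),
    master_seed = config$master_seed,
    package_version = as.character(utils::packageVersion("bimodalseed")),
    stages = lapply(stages, rel),
    results = list(
      active_shifts = shifts,
      is_word = is_word, cs_word = cs_word,
      is_word_peak = tw$peak_value[tw$word == is_word],
      cs_word_peak = tw$peak_value[tw$word == cs_word],
      is_word_rank = match(is_word, tw$word),
      class_n = vapply(dist4, `[[`, 0L, "n"),
      shifts_mean = as.list(gap$shifts),
      additivity_gap = gap$gap,
      additivity_ci = gap$ci,
      n_flagged_long_run = length(screen$flagged),
      n_positive_peaks = sum(peaks$positive),
      clip_overlap = ov,
      spearman_rho = sp$rho, spearman_p = sp$p))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  say("done (", round(proc.time()[["elapsed"]] - t0, 1), "s)")
  invisible(manifest)
}
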