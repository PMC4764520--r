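#' Parameter-recovery study: differential expression
#'
#' Simulates the four libraries with spiked fold changes, runs the read
#' cleaning / collapsing / conserved-matching / exact-test pipeline on one
#' comparison, and scores recovery of the spiked miRNAs. Recall counts a
#' spiked miRNA as recovered when it is called significant in the correct
#' direction; the empirical false-discovery proportion is the fraction of
#' significant calls that were not spiked in that pair.
#'
#' @param seed integer seed.
#' @param n_mirnas number of conserved miRNAs (default 300).
#' @param total reads per library (default 2e5).
#' @param n_spiked spiked miRNAs (default 30).
#' @param effect |log2 fold change| of the spikes (default 2).
#' @param pair comparison evaluated (default `"PF2S/PF2U"`).
#' @return list `recall`, `fdr`, `n_significant`, `n_spiked`.
#' @export
benchmark_de_recovery <- function(seed, n_mirnas = 300L, total = 2e5,
                                  n_spiked = 30L, effect = 2,
                                  pair = "PF2S/PF2U") {
  cfg <- simulation_config(
    seed = seed, n_conserved = n_mirnas, n_novel = 0L, n_transcripts = 2L,
    n_spiked = n_spiked, spike_log2fc = effect,
    library_totals = c(PF2U = total, PF2S = total, PF4U = total,
                       PF4S = total),
    degradome = list(n_targets = 0L, on_site_fraction = 0.8,
                     sig_length = 31L, background_positions = 12L,
                     background_rate = 0L, mismatch_range = 0:2))
  ref <- simulate_reference(cfg)
  sim <- simulate_srna_libraries(cfg, ref)
  libs <- strsplit(pair, "/", fixed = TRUE)[[1]]
  params <- cleaning_params(adapter3 = cfg$adapter)
  collapsed_list <- list()
  totals <- numeric(0)
  for (lib in libs) {
    cl <- clean_reads(sim$reads[[lib]], params)
    collapsed_list[[lib]] <- collapse_reads(cl$records, lib)
    totals[lib] <- cl$stats[["retained"]]
  }
  collapsed <- merge_collapsed(collapsed_list)
  hits <- match_conserved(collapsed, ref$mature_ref)
  mat <- expression_matrix(collapsed, hits)
  de <- compare_libraries(mat, totals, pair)

  sp <- sim$spikes[sim$spikes$pair == pair, ]
  sp$ref_id <- ref$mirna_truth$ref_id[match(sp$mirna, ref$mirna_truth$id)]
  de_sp <- de[match(sp$ref_id, de$id), ]
  recovered <- !is.na(de_sp$status) &
    ((sp$log2fc > 0 & de_sp$status == "up") |
       (sp$log2fc < 0 & de_sp$status == "down"))
  sig <- de$id[de$status %in% c("up", "down")]
  false_pos <- setdiff(sig, sp$ref_id)
  list(recall = mean(recovered),
       fdr = if (length(sig)) length(false_pos) / length(sig) else 0,
       n_significant = length(sig), n_spiked = nrow(sp))
}

#' Type-I error of the exact test on null count pairs
#'
#' Draws per-miRNA means from the configured log-normal, then two Poisson
#' counts per miRNA with the same mean (equal library totals), and reports
#' the fraction of two-sided P-values at or below `alpha`.
#'
#' @param seed integer seed.
#' @param n_mirnas number of null miRNAs (default 300).
#' @param total library total (default 2e5).
#' @param alpha significance level (default 0.05).
#' @return fraction of null P-values <= alpha.
#' @export
benchmark_null_type1 <- function(seed, n_mirnas = 300L, total = 2e5,
                                 alpha = 0.05) {
  with_artifact_seed(seed, "null_type1", {
    lam <- stats::rlnorm(n_mirnas, log(100), 1.2)
    x <- stats::rpois(n_mirnas, lam)
    y <- stats::rpois(n_mirnas, lam)
    p <- vapply(seq_len(n_mirnas), function(i) {
      ac_pvalue(x[i], y[i], total, total)$p
    }, numeric(1))
    mean(p <= alpha)
  })
}

#' Closed-loop check of the hairpin annotation criteria
#'
#' Every planted hairpin locus is excised from its host transcript, folded
#' and checked; every dinucleotide-shuffled control precursor is folded and
#' checked with the mature at the original coordinates and must fail with
#' at least one reason code.
#'
#' @param seed integer seed.
#' @param n number of planted hairpins (default 50).
#' @return list `planted_pass_rate`, `shuffled_fail_rate`,
#'   `shuffled_reasons` (table of first reason codes).
#' @export
benchmark_hairpin_criteria <- function(seed, n = 50L) {
  cfg <- simulation_config(
    seed = seed, n_conserved = n, n_novel = 0L, n_transcripts = 1L,
    n_spiked = 0L,
    degradome = list(n_targets = 0L, on_site_fraction = 0.8,
                     sig_length = 31L, background_positions = 12L,
                     background_rate = 0L, mismatch_range = 0:2))
  ref <- simulate_reference(cfg)
  pass <- logical(n)
  for (i in seq_len(n)) {
    tr <- ref$transcripts$sequence[ref$transcripts$id ==
                                     ref$mirna_truth$host[i]]
    wins <- excise_precursors(tr, ref$mirna_truth$mature_start0[i],
                              ref$mirna_truth$mature_end0[i], "+")
    for (w in seq_len(nrow(wins))) {
      verdict <- check_meyers(wins$sequence[w], wins$mature_start0[w],
                              wins$mature_end0[w])
      if (verdict$pass) { pass[i] <- TRUE; break }
    }
  }
  fails <- logical(n)
  reasons <- character(n)
  with_artifact_seed(seed, "shuffle_controls", {
    for (i in seq_len(n)) {
      prec <- shuffle_dinucleotide(ref$hairpins$precursor[i])
      verdict <- check_meyers(prec, ref$hairpins$mature_start0[i],
                              ref$hairpins$mature_end0[i])
      fails[i] <- !verdict$pass
      reasons[i] <- if (length(verdict$reasons)) verdict$reasons[1] else ""
    }
  })
  list(planted_pass_rate = mean(pass), shuffled_fail_rate = mean(fails),
       shuffled_reasons = table(reasons[fails]))
}

#' Closed-loop check of degradome target recovery
#'
#' Calls targets with the true miRNA set and scores site-exact recovery of
#' every planted cleavage site (category I), then repeats the calling with
#' dinucleotide-shuffled decoy miRNAs, which must produce no calls at the
#' strict score threshold.
#'
#' @param seed integer seed.
#' @param n_targets planted targets (default 50).
#' @param n_decoys shuffled decoy miRNAs (default 20).
#' @param strict_score decoy score threshold (default 2).
#' @return list `site_exact_recovery`, `category_I_rate`, `decoy_calls_strict`,
#'   `decoy_calls_reported`.
#' @export
benchmark_degradome_recovery <- function(seed, n_targets = 50L,
                                         n_decoys = 20L, strict_score = 2) {
  cfg <- simulation_config(
    seed = seed, n_conserved = max(50L, n_targets), n_novel = 0L,
    n_transcripts = n_targets, n_spiked = 0L,
    degradome = list(n_targets = n_targets, on_site_fraction = 0.8,
                     sig_length = 31L, background_positions = 12L,
                     background_rate = 2L, mismatch_range = 0:2))
  ref <- simulate_reference(cfg)
  dgs <- simulate_degradome(cfg, ref)
  mirnas <- ref$mirna_truth[, c("id", "sequence")]
  calls <- call_targets(mirnas, ref$transcripts, dgs$signatures)
  tt <- dgs$target_truth
  key <- paste(calls$mirna, calls$transcript, calls$cleavage_pos0)
  tkey <- paste(tt$mirna, tt$transcript, tt$cleavage_pos0)
  found <- tkey %in% key
  catI <- vapply(tkey, function(k) {
    i <- match(k, key)
    !is.na(i) && calls$category[i] == "I"
  }, logical(1))
  decoys <- with_artifact_seed(seed, "decoys", {
    idx <- seq_len(min(n_decoys, nrow(mirnas)))
    data.frame(id = paste0("decoy-", mirnas$id[idx]),
               sequence = vapply(mirnas$sequence[idx],
                                 shuffle_dinucleotide, character(1)),
               stringsAsFactors = FALSE)
  })
  dcalls <- call_targets(decoys, ref$transcripts, dgs$signatures)
  list(site_exact_recovery = mean(found),
       category_I_rate = mean(catI),
       decoy_calls_strict = if (nrow(dcalls))
         sum(dcalls$score <= strict_score) else 0L,
       decoy_calls_reported = nrow(dcalls))
}
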