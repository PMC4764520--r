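.rand_seq <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len[min(i, length(len))], replace = TRUE,
                 prob = p), collapse = "")
  }, character(1))
}

#' Simulation configuration
#'
#' Defaults define the study conditions emulated throughout the test suite:
#' four libraries (PF2U, PF2S, PF4U, PF4S) of 2e5 reads each, 300 conserved
#' and 10 novel miRNA loci, 30 miRNAs spiked at |log2fc| = 2 in both salt
#' comparisons, log-normal background abundances, ncRNA contaminants, poly-A
#' and low-quality reads, a TruSeq small-RNA 3' adapter, and a degradome
#' with 80 percent of a target transcript's 5'-end mass on the planted
#' cleavage site.
#'
#' @param seed integer seed; fixes every output bit-for-bit.
#' @param n_transcripts extra (non-hairpin) transcripts, used as degradome
#'   targets.
#' @param transcript_length length range (nt).
#' @param gc GC fraction of simulated sequence.
#' @param n_conserved,n_novel numbers of conserved / novel miRNA loci.
#' @param library_totals named read totals for the four libraries.
#' @param n_spiked,spike_log2fc spiked miRNA count and |log2 effect|
#'   (half up, half down, applied to PF2S/PF2U and PF4S/PF4U).
#' @param fractions named read-category fractions (miRNA, star, rRNA, tRNA,
#'   snRNA, snoRNA, polyA, lowqual; remainder is random degradation).
#' @param isomir_rate per-read probability of a 1-nt 3' isomiR.
#' @param abundance_meanlog,abundance_sdlog log-normal background abundance.
#' @param spike_meanlog,spike_sdlog abundance of spiked miRNAs (controlled
#'   spike-ins).
#' @param adapter 3' adapter appended to every read.
#' @param read_length sequencer read length (nt).
#' @param degradome list: `n_targets`, `on_site_fraction`, `sig_length`,
#'   `background_positions`, `background_rate` (signatures per non-target
#'   transcript), `mismatch_range` (designed site mismatches, never at
#'   miRNA positions 10/11).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_transcripts = 30L,
                              transcript_length = c(400L, 1200L),
                              gc = 0.5,
                              n_conserved = 300L,
                              n_novel = 10L,
                              library_totals = c(PF2U = 2e5, PF2S = 2e5,
                                                 PF4U = 2e5, PF4S = 2e5),
                              n_spiked = 30L,
                              spike_log2fc = 2,
                              fractions = c(miRNA = 0.40, star = 0.02,
                                            rRNA = 0.12, tRNA = 0.05,
                                            snRNA = 0.02, snoRNA = 0.01,
                                            polyA = 0.005, lowqual = 0.003),
                              isomir_rate = 0.05,
                              abundance_meanlog = log(100),
                              abundance_sdlog = 1.2,
                              spike_meanlog = log(200),
                              spike_sdlog = 0.8,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              read_length = 36L,
                              degradome = list(n_targets = 20L,
                                               on_site_fraction = 0.8,
                                               sig_length = 31L,
                                               background_positions = 12L,
                                               background_rate = 2L,
                                               mismatch_range = 0:2)) {
  stopifnot(sum(fractions) <= 1, spike_log2fc >= 0,
            n_spiked <= n_conserved)
  structure(list(seed = as.integer(seed), n_transcripts = n_transcripts,
                 transcript_length = transcript_length, gc = gc,
                 n_conserved = n_conserved, n_novel = n_novel,
                 library_totals = library_totals, n_spiked = n_spiked,
                 spike_log2fc = spike_log2fc, fractions = fractions,
                 isomir_rate = isomir_rate,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 spike_meanlog = spike_meanlog, spike_sdlog = spike_sdlog,
                 adapter = toupper(adapter), read_length = read_length,
                 degradome = degradome),
            class = "simulation_config")
}

# one Meyers-compliant hairpin around a mature sequence: an 8-nt stem
# extension on each side, an 11-nt loop drawn from {A,C} (no internal
# pairing), and a perfectly complementary star arm
.build_hairpin <- function(mature) {
  ext <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
               collapse = "")
  loop <- paste(sample(c("A", "C"), 11, replace = TRUE), collapse = "")
  precursor <- paste0(ext, mature, loop, revcomp(mature), revcomp(ext))
  list(precursor = precursor, mature_start0 = 8L,
       mature_end0 = 8L + nchar(mature),
       # the 2-nt 3' overhang star for a perfect duplex
       star = substr(precursor,
                     8L + nchar(mature) + 11L + 1L + 2L,
                     8L + nchar(mature) + 11L + nchar(mature) + 2L))
}

.mutate_seq <- function(s, k, avoid_pos = integer(0)) {
  if (k == 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(setdiff(seq_along(ch), avoid_pos), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate the reference sets and ground truth
#'
#' Builds transcripts with embedded Meyers-compliant hairpin loci, ncRNA
#' class references, a mature miRNA reference (conserved matures copied in
#' with 0-2 planted substitutions; novel matures absent), and planted
#' degradome target sites (designed mismatches never opposite miRNA
#' positions 10/11).
#'
#' @param config a [simulation_config()].
#' @return list `transcripts`, `ncrna` (list of class references),
#'   `mature_ref`, `hairpins`, `mirna_truth`, `target_truth`, `config`.
#' @export
simulate_reference <- function(config = simulation_config()) {
  with_artifact_seed(config$seed, "reference", {
    n_mir <- config$n_conserved + config$n_novel
    repeat {
      matures <- .rand_seq(n_mir, rep(21L, n_mir), config$gc)
      if (!anyDuplicated(matures)) break
    }
    ids <- c(sprintf("pfo-miR%03d", seq_len(config$n_conserved)),
             sprintf("pfo-mirN%02d", seq_len(config$n_novel)))
    is_novel <- c(rep(FALSE, config$n_conserved), rep(TRUE, config$n_novel))

    hp <- lapply(matures, .build_hairpin)
    # host transcripts, one per hairpin
    host_len <- sample(seq(config$transcript_length[1],
                           config$transcript_length[2]), n_mir,
                       replace = TRUE)
    hosts <- .rand_seq(n_mir, host_len, config$gc)
    ins <- integer(n_mir)
    for (i in seq_len(n_mir)) {
      plen <- nchar(hp[[i]]$precursor)
      ins[i] <- sample(seq(50L, host_len[i] - plen - 50L), 1)
      hosts[i] <- paste0(substr(hosts[i], 1, ins[i]), hp[[i]]$precursor,
                         substr(hosts[i], ins[i] + 1L, host_len[i]))
    }
    host_ids <- sprintf("HOST%04d", seq_len(n_mir))

    # extra transcripts; the first n_targets carry planted cleavage sites
    dg <- config$degradome
    n_extra <- max(config$n_transcripts, dg$n_targets)
    extra_len <- sample(seq(config$transcript_length[1],
                            config$transcript_length[2]), n_extra,
                        replace = TRUE)
    extras <- .rand_seq(n_extra, extra_len, config$gc)
    extra_ids <- sprintf("UN%04d", seq_len(n_extra))
    tgt <- list()
    for (t in seq_len(dg$n_targets)) {
      mi <- ((t - 1L) %% config$n_conserved) + 1L
      m <- nchar(matures[mi])
      site <- revcomp(matures[mi])
      k <- sample(dg$mismatch_range, 1)
      mm_pos <- if (k > 0) {
        sample(setdiff(seq_len(m), c(10L, 11L)), k)
      } else integer(0)
      ch <- strsplit(site, "", fixed = TRUE)[[1]]
      michar <- strsplit(matures[mi], "", fixed = TRUE)[[1]]
      for (p in mm_pos) {
        j <- m - p + 1L     # site index opposite miRNA position p
        bad <- c(chartr("ACGT", "TGCA", michar[p]),          # WC partner
                 if (michar[p] == "G") "T",                  # wobbles
                 if (michar[p] == "T") "G")
        ch[j] <- sample(setdiff(c("A", "C", "G", "T"), c(bad, ch[j])), 1)
      }
      site <- paste(ch, collapse = "")
      s0 <- sample(seq(60L, extra_len[t] - m - dg$sig_length - 30L), 1)
      extras[t] <- paste0(substr(extras[t], 1, s0),
                          site,
                          substr(extras[t], s0 + m + 1L, extra_len[t]))
      tgt[[t]] <- data.frame(mirna = ids[mi], transcript = extra_ids[t],
                             site_start0 = s0,
                             cleavage_pos0 = s0 + m - 10L,
                             designed_mismatches = k,
                             stringsAsFactors = FALSE)
    }
    target_truth <- do.call(rbind, tgt)

    transcripts <- data.frame(id = c(host_ids, extra_ids),
                              sequence = c(hosts, extras),
                              stringsAsFactors = FALSE)

    # mature reference: conserved matures with 0-2 planted substitutions
    ref_seq <- vapply(seq_len(config$n_conserved), function(i) {
      .mutate_seq(matures[i], sample(0:2, 1))
    }, character(1))
    mature_ref <- data.frame(id = sprintf("ref-miR%03d",
                                          seq_len(config$n_conserved)),
                             sequence = ref_seq, stringsAsFactors = FALSE)

    ncrna <- list(
      rRNA = data.frame(id = sprintf("rRNA%02d", 1:3),
                        sequence = .rand_seq(3, rep(1200L, 3), config$gc),
                        stringsAsFactors = FALSE),
      tRNA = data.frame(id = sprintf("tRNA%02d", 1:15),
                        sequence = .rand_seq(15, rep(75L, 15), config$gc),
                        stringsAsFactors = FALSE),
      snRNA = data.frame(id = sprintf("snRNA%02d", 1:6),
                         sequence = .rand_seq(6, rep(150L, 6), config$gc),
                         stringsAsFactors = FALSE),
      snoRNA = data.frame(id = sprintf("snoRNA%02d", 1:6),
                          sequence = .rand_seq(6, rep(120L, 6), config$gc),
                          stringsAsFactors = FALSE))

    hairpins <- data.frame(
      id = ids, precursor = vapply(hp, `[[`, "", "precursor"),
      mature_start0 = vapply(hp, `[[`, 0L, "mature_start0"),
      mature_end0 = vapply(hp, `[[`, 0L, "mature_end0"),
      star = vapply(hp, `[[`, "", "star"),
      host = host_ids, host_insert0 = ins, stringsAsFactors = FALSE)

    mirna_truth <- data.frame(
      id = ids, sequence = matures, is_novel = is_novel,
      ref_id = c(mature_ref$id, rep(NA_character_, config$n_novel)),
      host = host_ids,
      mature_start0 = ins + 8L, mature_end0 = ins + 8L + 21L,
      star = hairpins$star, stringsAsFactors = FALSE)

    list(transcripts = transcripts, ncrna = ncrna, mature_ref = mature_ref,
         hairpins = hairpins, mirna_truth = mirna_truth,
         target_truth = target_truth, config = config)
  })
}

.frag <- function(ref_seqs, n, len_range = 18:28) {
  if (n == 0) return(character(0))
  src <- sample(ref_seqs, n, replace = TRUE)
  len <- sample(len_range, n, replace = TRUE)
  len <- pmin(len, nchar(src))
  start <- vapply(seq_len(n), function(i) {
    sample.int(nchar(src[i]) - len[i] + 1L, 1)
  }, integer(1))
  substr(src, start, start + len - 1L)
}

#' Simulate the four sRNA libraries
#'
#' Per-miRNA abundances are log-normal (spiked miRNAs at a controlled
#' spike-in level, multiplied by `2^effect` in the numerator library of
#' their pair); reads are mature sequences (with a low rate of 1-nt 3'
#' isomiRs), star strands, ncRNA fragments, random degradation products,
#' poly-A and low-quality reads, each with the 3' adapter appended and
#' truncated to the read length. Written totals match the configured totals
#' exactly.
#'
#' @param config a [simulation_config()].
#' @param ref output of [simulate_reference()].
#' @param dir optional directory; when given, one FASTQ per library is
#'   written there.
#' @return list `reads` (named list of record data.frames),
#'   `expression_truth` (data.frame id, library, expected_count, spiked,
#'   direction), `spikes` (data.frame mirna, pair, log2fc), `paths`.
#' @export
simulate_srna_libraries <- function(config, ref, dir = NULL) {
  libs <- names(config$library_totals)
  n_mir <- nrow(ref$mirna_truth)
  spikes <- with_artifact_seed(config$seed, "spikes", {
    idx <- sample(seq_len(config$n_conserved), config$n_spiked)
    dirn <- rep(c(1, -1), length.out = config$n_spiked)
    do.call(rbind, lapply(c("PF2S/PF2U", "PF4S/PF4U"), function(p) {
      data.frame(mirna = ref$mirna_truth$id[idx], pair = p,
                 log2fc = dirn * config$spike_log2fc,
                 stringsAsFactors = FALSE)
    }))
  })
  abundance <- with_artifact_seed(config$seed, "abundance", {
    ab <- stats::rlnorm(n_mir, config$abundance_meanlog,
                        config$abundance_sdlog)
    sp <- unique(spikes$mirna)
    ab[match(sp, ref$mirna_truth$id)] <-
      stats::rlnorm(length(sp), config$spike_meanlog, config$spike_sdlog)
    ab
  })

  fr <- config$fractions
  truth <- list()
  reads <- list()
  paths <- character(0)
  for (lib in libs) {
    total <- as.integer(config$library_totals[[lib]])
    mult <- rep(1, n_mir)
    sel <- spikes[vapply(strsplit(spikes$pair, "/", fixed = TRUE),
                         `[`, "", 1) == lib, , drop = FALSE]
    if (nrow(sel)) {
      mult[match(sel$mirna, ref$mirna_truth$id)] <- 2^sel$log2fc
    }
    w <- abundance * mult
    p_mir <- fr[["miRNA"]] * w / sum(w)
    p_star <- fr[["star"]] * w / sum(w)
    probs <- c(p_mir, p_star,
               rRNA = fr[["rRNA"]], tRNA = fr[["tRNA"]],
               snRNA = fr[["snRNA"]], snoRNA = fr[["snoRNA"]],
               polyA = fr[["polyA"]], lowqual = fr[["lowqual"]],
               degradation = 1 - sum(fr))
    lib_out <- with_artifact_seed(config$seed, paste0("library:", lib), {
      cnt <- as.integer(stats::rmultinom(1, total, probs))
      mir_cnt <- cnt[seq_len(n_mir)]
      star_cnt <- cnt[n_mir + seq_len(n_mir)]
      rest <- cnt[2 * n_mir + 1:7]
      inserts <- character(0)
      for (i in which(mir_cnt > 0)) {
        m <- ref$mirna_truth$sequence[i]
        c_i <- mir_cnt[i]
        k <- stats::rbinom(1, c_i, config$isomir_rate)
        hp_prec <- ref$hairpins$precursor[i]
        ext_base <- substr(hp_prec, ref$hairpins$mature_end0[i] + 1L,
                           ref$hairpins$mature_end0[i] + 1L)
        variants <- if (k > 0) {
          v <- character(k)
          trim <- seq_len(k) %% 2 == 0
          v[trim] <- substr(m, 1, nchar(m) - 1L)
          v[!trim] <- paste0(m, ext_base)
          v
        } else character(0)
        inserts <- c(inserts, rep(m, c_i - k), variants)
      }
      for (i in which(star_cnt > 0)) {
        inserts <- c(inserts, rep(ref$hairpins$star[i], star_cnt[i]))
      }
      for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
        inserts <- c(inserts, .frag(ref$ncrna[[cl]]$sequence,
                                    rest[match(cl, c("rRNA", "tRNA",
                                                     "snRNA", "snoRNA"))]))
      }
      n_polyA <- rest[5]; n_lowq <- rest[6]; n_deg <- rest[7]
      inserts <- c(inserts,
                   strrep("A", sample(20:26, n_polyA, replace = TRUE)),
                   .rand_seq(n_lowq, sample(18:30, n_lowq, replace = TRUE),
                             config$gc),
                   .rand_seq(n_deg, sample(18:30, n_deg, replace = TRUE),
                             config$gc))
      lowq_flag <- c(rep(FALSE, length(inserts) - n_lowq - n_deg),
                     rep(TRUE, n_lowq), rep(FALSE, n_deg))
      o <- sample(length(inserts))
      inserts <- inserts[o]; lowq_flag <- lowq_flag[o]
      seqs <- substr(paste0(inserts, config$adapter, strrep("A", 40)),
                     1L, config$read_length)
      qual <- ifelse(lowq_flag, strrep("#", config$read_length),
                     strrep("I", config$read_length))
      data.frame(id = sprintf("%s_r%07d", lib, seq_along(seqs)),
                 sequence = seqs, quality = qual, stringsAsFactors = FALSE)
    })
    reads[[lib]] <- lib_out
    truth[[lib]] <- data.frame(
      id = ref$mirna_truth$id, library = lib,
      expected_count = as.numeric(total * p_mir),
      spiked = ref$mirna_truth$id %in% sel$mirna,
      direction = ifelse(ref$mirna_truth$id %in% sel$mirna,
                         sign(sel$log2fc[match(ref$mirna_truth$id,
                                               sel$mirna)]), 0),
      stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      p <- file.path(dir, paste0(lib, ".fastq"))
      write_fastq(lib_out, p)
      paths[lib] <- p
    }
  }
  list(reads = reads, expression_truth = do.call(rbind, truth),
       spikes = spikes, paths = paths)
}

#' Simulate a degradome signature library
#'
#' On-target signatures start exactly at the planted cleavage position
#' (opposite miRNA position 10); background 5' ends are uniform along the
#' transcripts, with per-target-transcript background mass set by the
#' on-site fraction.
#'
#' @param config a [simulation_config()].
#' @param ref output of [simulate_reference()].
#' @param dir optional directory; writes `degradome.fasta` in the collapsed
#'   header dialect when given.
#' @return list `signatures` (collapsed data.frame, library `DG`),
#'   `target_truth`, `path`.
#' @export
simulate_degradome <- function(config, ref, dir = NULL) {
  dg <- config$degradome
  tt <- ref$target_truth
  out <- with_artifact_seed(config$seed, "degradome", {
    seqs <- character(0); cnts <- integer(0)
    tseq <- stats::setNames(ref$transcripts$sequence, ref$transcripts$id)
    for (i in seq_len(nrow(tt))) {
      tr <- tseq[[tt$transcript[i]]]
      on_cnt <- stats::rpois(1, 40) + 10L
      seqs <- c(seqs, substr(tr, tt$cleavage_pos0[i] + 1L,
                             tt$cleavage_pos0[i] + dg$sig_length))
      cnts <- c(cnts, on_cnt)
      if (dg$on_site_fraction < 1) {
        bg_mass <- max(0L, round(on_cnt * (1 - dg$on_site_fraction) /
                                   dg$on_site_fraction))
        if (bg_mass > 0) {
          nb <- dg$background_positions
          pos <- sample(seq(0L, nchar(tr) - dg$sig_length), nb)
          pos <- setdiff(pos, tt$cleavage_pos0[i])
          share <- as.integer(stats::rmultinom(1, bg_mass,
                                               rep(1, length(pos))))
          keep <- share > 0
          seqs <- c(seqs, substring(tr, pos[keep] + 1L,
                                    pos[keep] + dg$sig_length))
          cnts <- c(cnts, share[keep])
        }
      }
    }
    # light background on transcripts without planted sites
    others <- setdiff(ref$transcripts$id, tt$transcript)
    for (id in others) {
      nb <- stats::rpois(1, dg$background_rate)
      if (nb == 0) next
      tr <- tseq[[id]]
      if (nchar(tr) <= dg$sig_length) next
      pos <- sample(seq(0L, nchar(tr) - dg$sig_length), min(nb, 5L))
      seqs <- c(seqs, substring(tr, pos + 1L, pos + dg$sig_length))
      cnts <- c(cnts, rep(1L, length(pos)))
    }
    agg <- tapply(cnts, seqs, sum)
    sig <- data.frame(sequence = names(agg), stringsAsFactors = FALSE)
    sig$DG <- as.integer(unname(agg))
    sig[order(-sig$DG, sig$sequence), , drop = FALSE]
  })
  rownames(out) <- NULL
  path <- NULL
  if (!is.null(dir)) {
    path <- file.path(dir, "degradome.fasta")
    write_collapsed_fasta(out, "DG", path)
  }
  list(signatures = out, target_truth = tt, path = path)
}
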