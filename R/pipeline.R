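.default_pairs <- c("PF2S/PF2U", "PF4U/PF2U", "PF4S/PF4U", "PF4S/PF2S")

#' Validate a pipeline configuration
#'
#' Collects every problem and reports them together rather than stopping at
#' the first.
#'
#' @param config path to a YAML file, or an already-parsed list.
#' @return list `ok` (logical) and `errors` (character vector).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  if (is.character(config)) {
    if (!file.exists(config)) {
      return(list(ok = FALSE, errors = sprintf("config file '%s' not found",
                                               config)))
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config) || !is.list(config) || length(config) == 0) {
    return(list(ok = FALSE, errors = "config is empty"))
  }
  if (is.null(config$seed)) errors <- c(errors, "missing field: seed")
  sim <- config$simulate
  totals <- if (!is.null(sim$library_totals)) unlist(sim$library_totals)
  else eval(formals(simulation_config)$library_totals)
  libs <- names(totals)
  pairs <- config$pairs %||% .default_pairs
  for (p in pairs) {
    ab <- strsplit(p, "/", fixed = TRUE)[[1]]
    if (length(ab) != 2 || !all(ab %in% libs)) {
      errors <- c(errors, sprintf("pair '%s' references undeclared libraries",
                                  p))
    }
  }
  for (f in config$inputs) {
    if (!file.exists(f)) {
      errors <- c(errors, sprintf("input file '%s' does not exist", f))
    }
  }
  if (!is.null(sim)) {
    bad <- setdiff(names(sim), names(formals(simulation_config)))
    if (length(bad)) {
      errors <- c(errors, sprintf("unknown simulate parameter: %s",
                                  paste(bad, collapse = ", ")))
    }
  }
  list(ok = length(errors) == 0, errors = errors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# most abundant read sequence per catalog id (the representative mature)
.catalog_sequences <- function(collapsed, hits) {
  libs <- .lib_cols(collapsed)
  tot <- rowSums(collapsed[, libs, drop = FALSE])
  cnt <- tot[match(hits$sequence, collapsed$sequence)]
  cnt[is.na(cnt)] <- 0
  o <- order(hits$ref_id, -cnt, hits$sequence)
  h <- hits[o, ]
  h[!duplicated(h$ref_id), c("ref_id", "sequence")]
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Stages run in dependency order: simulate, preprocess (clean / collapse /
#' length distributions), annotate (classes and the annotation summary),
#' catalog (conserved matching and novel hairpin discovery), differential
#' expression over the configured pairs with the salt-associated set logic,
#' and degradome target calling. Every output TSV carries a provenance
#' comment (package version, seed, parameter hash); rerunning with the
#' same config is byte-identical.
#'
#' @param config path to YAML or a list: fields `seed`, optional `simulate`
#'   (overrides for [simulation_config()]), `pairs`, `cleaning` (overrides
#'   for [cleaning_params()]), `novel_max_candidates`, `degradome_max_score`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list of the main in-memory results.
#' @export
run_all <- function(config, outdir) {
  v <- validate_config(config)
  if (!v$ok) stop(paste(v$errors, collapse = "; "))
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("salmir %s seed=%s params=%s",
                   as.character(utils::packageVersion("salmir")),
                   config$seed, .param_hash(config))
  sim_args <- config$simulate %||% list()
  sim_args$seed <- config$seed
  cfg <- do.call(simulation_config, sim_args)
  pairs <- config$pairs %||% .default_pairs

  ## simulate
  ref <- simulate_reference(cfg)
  libs_sim <- simulate_srna_libraries(cfg, ref)
  dg <- simulate_degradome(cfg, ref)
  write_fasta(ref$transcripts, file.path(outdir, "transcripts.fasta"))
  write_fasta(ref$mature_ref, file.path(outdir, "mature_reference.fasta"),
              rna = TRUE)

  ## preprocess
  cl_args <- config$cleaning %||% list()
  cl_args$adapter3 <- cl_args$adapter3 %||% cfg$adapter
  params <- do.call(cleaning_params, cl_args)
  collapsed_list <- list()
  totals <- numeric(0)
  ld_rows <- list()
  for (lib in names(cfg$library_totals)) {
    cl <- clean_reads(libs_sim$reads[[lib]], params)
    cc <- collapse_reads(cl$records, lib)
    collapsed_list[[lib]] <- cc
    totals[lib] <- cl$stats[["retained"]]
    write_collapsed_fasta(cc, lib, file.path(outdir,
                                             paste0(lib, "_collapsed.fasta")))
    ld <- length_distribution(cc, lib)
    ld_rows[[lib]] <- cbind(library = lib, ld)
  }
  collapsed <- merge_collapsed(collapsed_list)
  write_tsv(do.call(rbind, ld_rows), file.path(outdir, "length_dist.tsv"),
            stamp)

  ## annotate
  hits <- match_conserved(collapsed, ref$mature_ref)
  classes <- classify_reads(collapsed, ref$ncrna,
                            mirna_hits = hits$sequence)
  summ <- summarize_annotation(collapsed, classes)
  write_tsv(summ$counts, file.path(outdir, "annotation_summary.tsv"), stamp)
  write_tsv(summ$percent, file.path(outdir, "annotation_percent.tsv"), stamp)

  ## catalog
  cons_seq <- .catalog_sequences(collapsed, hits)
  cons_mat <- expression_matrix(collapsed, hits)
  conserved <- data.frame(id = rownames(cons_mat),
                          sequence = cons_seq$sequence[
                            match(rownames(cons_mat), cons_seq$ref_id)],
                          as.data.frame(cons_mat),
                          stringsAsFactors = FALSE)
  write_tsv(conserved, file.path(outdir, "conserved.tsv"), stamp)

  unann <- names(classes)[classes == "unannotated"]
  nmax <- config$novel_max_candidates %||% 300L
  tot_cnt <- rowSums(collapsed[, .lib_cols(collapsed), drop = FALSE])
  cand <- collapsed$sequence[collapsed$sequence %in% unann]
  cand <- cand[order(-tot_cnt[match(cand, collapsed$sequence)], cand)]
  cand <- cand[nchar(cand) >= 18 & nchar(cand) <= 25]
  cand <- utils::head(cand, nmax)
  novel <- discover_novel(collapsed, cand, ref$transcripts,
                          exclude_seqs = hits$sequence)
  write_tsv(novel, file.path(outdir, "novel.tsv"), stamp)

  ## differential expression
  mat <- cons_mat
  if (nrow(novel) > 0) {
    nov_assign <- data.frame(sequence = novel$sequence, ref_id = novel$id,
                             stringsAsFactors = FALSE)
    mat <- rbind(mat, expression_matrix(collapsed, nov_assign))
  }
  de <- list()
  dir.create(file.path(outdir, "de"), showWarnings = FALSE)
  for (p in pairs) {
    d <- compare_libraries(mat, totals, p)
    de[[p]] <- d
    write_tsv(d, file.path(outdir, "de",
                           paste0(gsub("/", "_vs_", p), ".tsv")), stamp)
  }
  salt <- NULL
  if (all(.default_pairs %in% pairs)) {
    salt <- salt_associated(de[["PF2S/PF2U"]], de[["PF4S/PF4U"]],
                            de[["PF4S/PF2S"]], de[["PF4U/PF2U"]])
    sdf <- data.frame(
      id = salt$salt_responsive,
      cross_ploidy = salt$salt_responsive %in% salt$cross_ploidy,
      tolerance_candidate = salt$salt_responsive %in%
        salt$tolerance_candidates, stringsAsFactors = FALSE)
    write_tsv(sdf, file.path(outdir, "salt_associated.tsv"), stamp)
  }

  ## degradome
  cat_mirnas <- rbind(
    data.frame(id = conserved$id, sequence = conserved$sequence,
               stringsAsFactors = FALSE),
    if (nrow(novel) > 0) data.frame(id = novel$id, sequence = novel$sequence,
                                    stringsAsFactors = FALSE))
  cat_mirnas <- cat_mirnas[!is.na(cat_mirnas$sequence), ]
  max_score <- config$degradome_max_score %||% 4
  targets <- call_targets(cat_mirnas, ref$transcripts, dg$signatures,
                          max_score = max_score)
  write_tsv(targets, file.path(outdir, "targets.tsv"), stamp)
  dir.create(file.path(outdir, "tplot"), showWarnings = FALSE)
  tplots <- attr(targets, "tplots")
  for (t in unique(targets$transcript)) {
    prof <- tplots[[t]]$counts
    nz <- which(prof > 0)
    write_tsv(data.frame(position0 = nz - 1L, count = prof[nz]),
              file.path(outdir, "tplot", paste0(t, ".tsv")), stamp)
  }

  invisible(list(reference = ref, collapsed = collapsed, totals = totals,
                 annotation = summ, conserved = conserved, novel = novel,
                 de = de, salt = salt, targets = targets))
}
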