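#' Cleaning parameters for raw sRNA reads
#'
#' Numeric defaults for the quality and contaminant filters: minimum mean
#' Phred 20, no ambiguous bases, poly-A when >= 80 percent A, inserts kept
#' between 18 and 30 nt. All are overridable.
#'
#' @param adapter3 3' adapter sequence (DNA letters).
#' @param max_adapter_mismatch mismatches tolerated when locating the
#'   adapter.
#' @param min_len,max_len insert length bounds (nt), inclusive.
#' @param min_mean_quality minimum mean Phred score of the retained insert.
#' @param polyA_fraction discard inserts whose A fraction is >= this value;
#'   must exceed 0.5.
#' @param min_overlap minimum adapter/read overlap (nt) for a match at the
#'   read's 3' end.
#' @return list of class `cleaning_params`.
#' @export
cleaning_params <- function(adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            max_adapter_mismatch = 1L,
                            min_len = 18L, max_len = 30L,
                            min_mean_quality = 20,
                            polyA_fraction = 0.8,
                            min_overlap = 5L) {
  stopifnot(min_len <= max_len, polyA_fraction > 0.5)
  structure(list(adapter3 = toupper(as_dna(adapter3)),
                 max_adapter_mismatch = as.integer(max_adapter_mismatch),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_mean_quality = min_mean_quality,
                 polyA_fraction = polyA_fraction,
                 min_overlap = as.integer(min_overlap)),
            class = "cleaning_params")
}

# locate the 3' adapter in each unique sequence: best prefix-anchored match
# (fewest mismatches, then leftmost) with <= max_mismatch mismatches over an
# overlap of >= min_overlap nt. Returns insert length (nchar if no adapter).
.find_adapter <- function(seqs, adapter, max_mm, min_overlap) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  len <- nchar(seqs)
  width <- max(len)
  mat <- .seq_matrix(seqs, width)
  alen <- nchar(adapter)
  aletters <- strsplit(adapter, "", fixed = TRUE)[[1]]
  best_pos <- rep(NA_integer_, n)   # adapter start (1-based)
  best_mm <- rep(Inf, n)
  for (s in seq_len(width)) {
    ov <- pmin(alen, len - s + 1L)
    cand <- which(ov >= min_overlap)
    if (!length(cand)) next
    span <- min(alen, width - s + 1L)
    sub <- mat[cand, seq.int(s, s + span - 1L), drop = FALSE]
    cmp <- sub != matrix(aletters[seq_len(span)], nrow = length(cand),
                         ncol = span, byrow = TRUE)
    mm <- rowSums(cmp, na.rm = TRUE)
    ok <- which(mm <= max_mm & mm < best_mm[cand])
    if (length(ok)) {
      idx <- cand[ok]
      best_mm[idx] <- mm[ok]
      best_pos[idx] <- s
    }
  }
  ifelse(is.na(best_pos), len, best_pos - 1L)
}

#' Clean raw sRNA reads
#'
#' Locates the 3' adapter (best prefix-anchored match allowing up to
#' `max_adapter_mismatch` mismatches), truncates each read before it, then
#' discards inserts that are too short, too long, of low mean quality,
#' contain `N`, or are poly-A. Filters are applied in that order and each
#' read is charged to the first rule it fails, so retained plus discarded
#' always equals the input count.
#'
#' @param records data.frame from [read_fastq()] or [read_fasta()].
#' @param params a [cleaning_params()] object.
#' @return list with `records` (cleaned data.frame) and `stats` (named
#'   integer vector of per-rule removal counts plus `input` and `retained`).
#' @export
clean_reads <- function(records, params = cleaning_params()) {
  stats <- c(input = nrow(records), adapter_trimmed = 0L, too_short = 0L,
             too_long = 0L, low_quality = 0L, ambiguous = 0L, polyA = 0L,
             retained = 0L)
  if (nrow(records) == 0) return(list(records = records, stats = stats))
  seqs <- as_dna(toupper(records$sequence))
  uniq <- unique(seqs)
  ins_u <- .find_adapter(uniq, params$adapter3, params$max_adapter_mismatch,
                         params$min_overlap)
  ins_len <- ins_u[match(seqs, uniq)]
  stats["adapter_trimmed"] <- sum(ins_len < nchar(seqs))
  insert <- substr(seqs, 1L, ins_len)

  drop <- rep("", length(insert))
  drop[ins_len < params$min_len] <- "too_short"
  sel <- drop == "" & ins_len > params$max_len
  drop[sel] <- "too_long"
  if (!all(is.na(records$quality))) {
    qual <- substr(records$quality, 1L, ins_len)
    mq <- vapply(qual, function(q) {
      if (is.na(q) || nchar(q) == 0) return(Inf)
      mean(utf8ToInt(q)) - 33
    }, numeric(1), USE.NAMES = FALSE)
    sel <- drop == "" & mq < params$min_mean_quality
    drop[sel] <- "low_quality"
  }
  sel <- drop == "" & grepl("N", insert, fixed = TRUE)
  drop[sel] <- "ambiguous"
  a_frac <- (nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))) /
    pmax(nchar(insert), 1L)
  sel <- drop == "" & a_frac >= params$polyA_fraction
  drop[sel] <- "polyA"

  for (rule in c("too_short", "too_long", "low_quality", "ambiguous", "polyA")) {
    stats[rule] <- sum(drop == rule)
  }
  keep <- drop == ""
  stats["retained"] <- sum(keep)
  out <- records[keep, , drop = FALSE]
  out$sequence <- insert[keep]
  out$quality <- ifelse(is.na(out$quality), NA_character_,
                        substr(out$quality, 1L, ins_len[keep]))
  rownames(out) <- NULL
  list(records = out, stats = stats)
}

#' Collapse cleaned reads to unique sequences
#'
#' @param records cleaned read data.frame.
#' @param library library id for the count column.
#' @return collapsed-read data.frame (`sequence` + count column); the sum of
#'   counts equals `nrow(records)`.
#' @export
collapse_reads <- function(records, library = "L1") {
  if (nrow(records) == 0) {
    out <- data.frame(sequence = character(), stringsAsFactors = FALSE)
    out[[library]] <- integer(0)
    return(out)
  }
  tab <- table(records$sequence)
  out <- data.frame(sequence = names(tab), stringsAsFactors = FALSE)
  out[[library]] <- as.integer(tab)
  out[order(out$sequence), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Read-length distribution of a library
#'
#' @param collapsed collapsed-read data.frame.
#' @param library library id.
#' @param unique_reads count each unique sequence once instead of weighting
#'   by abundance?
#' @return data.frame `length`, `count`, `fraction` (zero-count lengths
#'   omitted; fractions sum to 1).
#' @export
length_distribution <- function(collapsed, library, unique_reads = FALSE) {
  cnt <- collapsed[[library]]
  if (is.null(cnt)) stop(sprintf("unknown library id '%s'", library))
  keep <- cnt > 0
  len <- nchar(collapsed$sequence[keep])
  w <- if (unique_reads) rep(1L, sum(keep)) else cnt[keep]
  agg <- tapply(w, len, sum)
  out <- data.frame(length = as.integer(names(agg)),
                    count = as.numeric(agg))
  out <- out[order(out$length), , drop = FALSE]
  out$fraction <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

# grouped-by-width PDict matching of short reads against a reference set;
# returns data.frame(sequence, ref, start0, strand) for exact hits
.pdict_hits <- function(seqs, ref_ids, ref_seqs, strand) {
  hits <- list()
  subject <- Biostrings::DNAStringSet(ref_seqs)
  ok <- !grepl("[^ACGT]", seqs)
  by_len <- split(which(ok), nchar(seqs[ok]))
  for (grp in by_len) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[grp]))
    for (r in seq_along(subject)) {
      m <- Biostrings::matchPDict(pd, subject[[r]])
      st <- Biostrings::startIndex(m)
      nz <- which(lengths(st) > 0)
      for (p in nz) {
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = seqs[grp[p]], ref = ref_ids[r],
          start0 = st[[p]] - 1L, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(sequence = character(), ref = character(),
                      start0 = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Perfect-match mapping of reads onto a reference set
#'
#' Exact substring matches on the forward strand and as reverse complement.
#' Positions are 0-based half-open on the forward coordinate of the
#' reference; all occurrences are reported.
#'
#' @param seqs character vector of read sequences (DNA), or a collapsed-read
#'   data.frame.
#' @param reference data.frame with `id` and `sequence` (DNA).
#' @return data.frame `sequence`, `ref`, `start0`, `end0`, `strand`.
#' @export
map_perfect <- function(seqs, reference) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  if (nrow(reference) == 0) stop("empty reference")
  seqs <- unique(as_dna(toupper(seqs)))
  ref_seqs <- as_dna(toupper(reference$sequence))
  fwd <- .pdict_hits(seqs, reference$id, ref_seqs, "+")
  # a read maps to '-' where its reverse complement occurs on the forward ref
  rc <- revcomp(seqs)
  rev_raw <- .pdict_hits(rc, reference$id, ref_seqs, "-")
  if (nrow(rev_raw)) rev_raw$sequence <- seqs[match(rev_raw$sequence, rc)]
  out <- rbind(fwd, rev_raw)
  if (nrow(out)) {
    out$end0 <- out$start0 + nchar(out$sequence)
    out <- out[order(out$sequence, out$ref, out$start0, out$strand),
               c("sequence", "ref", "start0", "end0", "strand")]
    rownames(out) <- NULL
  } else {
    out$end0 <- integer(0)
    out <- out[, c("sequence", "ref", "start0", "end0", "strand")]
  }
  out
}

.CLASS_ORDER <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA")

#' Classify reads into sRNA annotation classes
#'
#' Each read gets exactly one class. Membership in an ncRNA class is a
#' perfect match into that class's reference set (either strand); reads in
#' `mirna_hits` are miRNA. Overlaps resolve by the fixed precedence
#' miRNA > rRNA > tRNA > snRNA > snoRNA > unannotated.
#'
#' @param seqs character vector of read sequences (or collapsed-read
#'   data.frame).
#' @param class_refs named list (names among rRNA, tRNA, snRNA, snoRNA) of
#'   reference data.frames (`id`, `sequence`).
#' @param mirna_hits character vector of sequences identified as miRNA.
#' @return named character vector: class per input sequence.
#' @export
classify_reads <- function(seqs, class_refs = list(), mirna_hits = character(0)) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  stopifnot(all(names(class_refs) %in% c("rRNA", "tRNA", "snRNA", "snoRNA")))
  cls <- rep("unannotated", length(seqs))
  names(cls) <- seqs
  for (cn in rev(intersect(.CLASS_ORDER, names(class_refs)))) {
    ref <- class_refs[[cn]]
    if (is.null(ref) || nrow(ref) == 0) next
    hit <- map_perfect(seqs, ref)
    cls[seqs %in% hit$sequence] <- cn
  }
  cls[seqs %in% mirna_hits] <- "miRNA"
  cls
}

#' Percentage with the printed-table rounding rule
#'
#' `100 * count / total`, rounded half away from zero to two decimals.
#'
#' @param count,total non-negative numbers, `total > 0`.
#' @return numeric percentage.
#' @export
annotation_percentage <- function(count, total) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, 2)
}

#' Per-library annotation summary of sRNA classes
#'
#' One row per library and measure (unique / total) with per-class counts
#' and a grand total; internal sums are exact by construction and the
#' percentages follow [annotation_percentage()].
#'
#' @param collapsed collapsed-read data.frame covering all libraries.
#' @param classes named character vector from [classify_reads()] (names are
#'   sequences).
#' @return list with `counts` (data.frame library, measure, total, miRNA,
#'   rRNA, snRNA, snoRNA, tRNA, unannotated) and `percent` (same shape,
#'   percentages).
#' @export
summarize_annotation <- function(collapsed, classes) {
  libs <- .lib_cols(collapsed)
  cls <- unname(classes[match(collapsed$sequence, names(classes))])
  if (anyNA(cls)) stop("every read must be classified")
  class_names <- c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "unannotated")
  rows <- list()
  for (lib in libs) {
    cnt <- collapsed[[lib]]
    present <- cnt > 0
    for (measure in c("unique", "total")) {
      w <- if (measure == "unique") as.integer(present) else cnt
      per <- vapply(class_names, function(cn) sum(w[cls == cn]), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        library = lib, measure = measure, total = sum(per),
        as.list(per), stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  percent <- counts
  for (cn in c("total", class_names)) {
    percent[[cn]] <- ifelse(counts$total > 0,
                            annotation_percentage(counts[[cn]], counts$total),
                            0)
  }
  list(counts = counts, percent = percent)
}
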