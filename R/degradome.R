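#' Map degradome signatures onto transcripts
#'
#' Exact forward-strand substring matches only (degradome 5' ends come from
#' the mRNA sense strand); every occurrence is reported. Position is the
#' signature's 5' end, 0-based.
#'
#' @param signatures collapsed-read data.frame (`sequence` + count column)
#'   or character vector.
#' @param transcripts data.frame `id`, `sequence`.
#' @return data.frame `sequence`, `transcript`, `position0`, `count`.
#' @export
map_signatures <- function(signatures, transcripts) {
  if (nrow(transcripts) == 0) stop("empty transcript set")
  if (is.character(signatures)) {
    sig <- data.frame(sequence = signatures, count = 1L,
                      stringsAsFactors = FALSE)
  } else {
    lib <- .lib_cols(signatures)[1]
    sig <- data.frame(sequence = signatures$sequence,
                      count = signatures[[lib]], stringsAsFactors = FALSE)
  }
  hits <- .pdict_hits(unique(as_dna(toupper(sig$sequence))), transcripts$id,
                      as_dna(toupper(transcripts$sequence)), "+")
  if (!nrow(hits)) {
    return(data.frame(sequence = character(), transcript = character(),
                      position0 = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(sequence = hits$sequence, transcript = hits$ref,
                    position0 = hits$start0,
                    count = sig$count[match(hits$sequence, sig$sequence)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript, out$position0, out$sequence), ]
  rownames(out) <- NULL
  out
}

#' Extend a mapped signature into a target-site window
#'
#' The window adds `upstream` nt of upstream transcript sequence to the
#' signature: `[max(0, position - upstream), position + signature_length)`.
#' Windows clipped at the transcript start are flagged truncated.
#'
#' @param transcript_seq transcript sequence.
#' @param position0 0-based signature 5'-end position.
#' @param signature_length signature length (nt).
#' @param upstream upstream extension (default 15 nt).
#' @return list `start0`, `end0`, `sequence`, `truncated`.
#' @export
extend_site <- function(transcript_seq, position0, signature_length,
                        upstream = 15L) {
  len <- nchar(transcript_seq)
  stopifnot(position0 >= 0, position0 < len)
  start0 <- max(0L, position0 - upstream)
  end0 <- min(len, position0 + signature_length)
  list(start0 = start0, end0 = end0,
       sequence = substr(transcript_seq, start0 + 1L, end0),
       truncated = position0 - upstream < 0 ||
         position0 + signature_length > len)
}

# penalty matrix for a set of site sequences against one miRNA:
# WC pair 0, G:U wobble 0.5, mismatch/unpaired 1; positions 10 and 11
# (1-based from the miRNA 5' end) doubled
.score_sites <- function(mirna, site_seqs) {
  m <- nchar(mirna)
  mi <- strsplit(as_dna(toupper(mirna)), "", fixed = TRUE)[[1]]
  rc <- revcomp(site_seqs)   # aligns site 3' end opposite miRNA 5' end
  mat <- .seq_matrix(rc, m)
  pen <- matrix(1, nrow = length(site_seqs), ncol = m)
  for (i in seq_len(m)) {
    col <- mat[, i]
    pen[!is.na(col) & col == mi[i], i] <- 0
    # rc letter 'A' derives from site 'T': miRNA G : site T is a wobble;
    # rc letter 'C' derives from site 'G': miRNA T : site G is a wobble
    if (mi[i] == "G") pen[!is.na(col) & col == "A", i] <- 0.5
    if (mi[i] == "T") pen[!is.na(col) & col == "C", i] <- 0.5
  }
  wt <- rep(1, m)
  wt[c(10, 11)[c(10, 11) <= m]] <- 2
  as.numeric(pen %*% wt)
}

#' Score one miRNA against a candidate target site
#'
#' The site window is reverse complemented and compared position-wise to
#' the miRNA (no gaps): Watson-Crick pair 0, G:U wobble 0.5, mismatch or
#' unpaired overhang 1.0; penalties at miRNA positions 10 and 11 are
#' doubled. An alignment is returned only when the score is at most
#' `max_score`.
#'
#' @param mirna_id,mirna_seq miRNA id and sequence.
#' @param transcript_id,transcript_seq transcript id and sequence.
#' @param site_start0 0-based start of the miRNA-complementary site.
#' @param cleavage_mirna_pos miRNA nucleotide (10 or 11) opposite the
#'   cleavage.
#' @param max_score reporting threshold (default 4).
#' @return one-row data.frame (miRNA, transcript, site coordinates, score,
#'   cleavage position, alignment strings) or `NULL`.
#' @export
score_site <- function(mirna_id, mirna_seq, transcript_id, transcript_seq,
                       site_start0, cleavage_mirna_pos = 10L, max_score = 4) {
  m <- nchar(mirna_seq)
  len <- nchar(transcript_seq)
  if (site_start0 < 0 || site_start0 + m > len) return(NULL)
  site <- substr(transcript_seq, site_start0 + 1L, site_start0 + m)
  if (nchar(site) < m) return(NULL)
  sc <- .score_sites(mirna_seq, site)
  if (sc > max_score) return(NULL)
  cleav0 <- site_start0 + m - cleavage_mirna_pos
  # alignment strings: site 5'->3' on top, miRNA 3'->5' underneath
  mi <- strsplit(as_dna(toupper(mirna_seq)), "", fixed = TRUE)[[1]]
  st <- strsplit(as_dna(toupper(site)), "", fixed = TRUE)[[1]]
  mir_rev <- rev(mi)
  marks <- vapply(seq_len(m), function(i) {
    pair <- paste0(mir_rev[i], st[i])
    if (pair %in% c("AT", "TA", "GC", "CG")) "|"
    else if (pair %in% c("GT", "TG")) "o"
    else " "
  }, character(1))
  data.frame(mirna = mirna_id, transcript = transcript_id,
             site_start0 = site_start0, site_end0 = site_start0 + m,
             score = sc, cleavage_pos0 = cleav0,
             cleavage_mirna_pos = as.integer(cleavage_mirna_pos),
             site_5to3 = paste(st, collapse = ""),
             match_line = paste(marks, collapse = ""),
             mirna_3to5 = as_rna(paste(mir_rev, collapse = "")),
             stringsAsFactors = FALSE)
}

#' Validate a cleavage position against the 10th/11th-nucleotide rule
#'
#' TRUE iff the signature's 5' end sits on the transcript nucleotide paired
#' with miRNA position 10 or 11 (1-based from the miRNA 5' end).
#'
#' @param alignment one-row data.frame from [score_site()].
#' @param signature_pos0 0-based transcript position of the signature 5' end.
#' @return logical.
#' @export
validate_cleavage <- function(alignment, signature_pos0) {
  m <- alignment$site_end0 - alignment$site_start0
  signature_pos0 %in% (alignment$site_start0 + m - c(10L, 11L))
}

#' Per-transcript degradome profile (t-plot)
#'
#' Accumulates signature abundances at their 5'-end positions; total
#' profile mass equals the total mapped signature count.
#'
#' @param transcript_id transcript id.
#' @param transcript_length transcript length (nt).
#' @param mapped data.frame from [map_signatures()] (any transcripts;
#'   filtered internally).
#' @return list `transcript`, `length`, `counts` (numeric vector indexed by
#'   0-based position + 1).
#' @export
build_tplot <- function(transcript_id, transcript_length, mapped) {
  counts <- numeric(transcript_length)
  sel <- mapped$transcript == transcript_id
  if (any(sel)) {
    agg <- tapply(mapped$count[sel], mapped$position0[sel], sum)
    counts[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  }
  list(transcript = transcript_id, length = transcript_length,
       counts = counts)
}

#' Assign a degradome category to a cleavage site
#'
#' Category I: the cleavage-site count is the unique transcript-wide
#' maximum. Category II: greater than the median of the non-zero positions
#' but not the unique maximum. Category III: the rest.
#'
#' @param profile numeric vector of per-position 5'-end counts (a t-plot).
#' @param cleavage_pos0 0-based cleavage position; its count must be >= 1.
#' @return `"I"`, `"II"` or `"III"`.
#' @export
categorize_site <- function(profile, cleavage_pos0) {
  stopifnot(any(profile > 0))
  cnt <- profile[cleavage_pos0 + 1L]
  stopifnot(cnt >= 1)
  mx <- max(profile)
  if (cnt == mx && sum(profile == mx) == 1) return("I")
  med <- stats::median(profile[profile > 0])
  if (cnt > med) "II" else "III"
}

#' Call miRNA targets from degradome signatures
#'
#' Composition of the degradome operations: signatures are mapped exactly
#' onto transcripts, each 5'-end position is tested as a cleavage site
#' opposite miRNA position 10 and 11 for every miRNA, alignments scoring
#' at most `max_score` are kept, and each call gets a t-plot category.
#' Calls are deduplicated by (miRNA, transcript, cleavage position),
#' keeping the better score, and sorted by category then score.
#'
#' @param mirnas data.frame `id`, `sequence`.
#' @param transcripts data.frame `id`, `sequence`.
#' @param signatures collapsed degradome reads (`sequence` + count).
#' @param max_score reporting threshold (default 4).
#' @return data.frame of target calls with `category` and per-site degradome
#'   counts; attribute `tplots` holds the per-transcript profiles.
#' @export
call_targets <- function(mirnas, transcripts, signatures, max_score = 4) {
  mapped <- map_signatures(signatures, transcripts)
  empty <- data.frame(mirna = character(), transcript = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(mapped)) return(empty)
  tlen <- stats::setNames(nchar(transcripts$sequence), transcripts$id)
  tseq <- stats::setNames(as_dna(toupper(transcripts$sequence)),
                          transcripts$id)
  tplots <- lapply(transcripts$id, function(t)
    build_tplot(t, tlen[[t]], mapped))
  names(tplots) <- transcripts$id

  pos_tab <- unique(mapped[, c("transcript", "position0")])
  calls <- list()
  for (k in seq_len(nrow(mirnas))) {
    mid <- mirnas$id[k]
    mseq <- as_dna(toupper(mirnas$sequence[k]))
    m <- nchar(mseq)
    for (cpos in c(10L, 11L)) {
      ss <- pos_tab$position0 + cpos - m
      ok <- which(ss >= 0 &
                    ss + m <= tlen[pos_tab$transcript] &
                    nchar(mseq) >= cpos)
      if (!length(ok)) next
      sites <- substr(tseq[pos_tab$transcript[ok]], ss[ok] + 1L, ss[ok] + m)
      scores <- .score_sites(mseq, sites)
      hit <- which(scores <= max_score)
      for (h in hit) {
        i <- ok[h]
        tr <- pos_tab$transcript[i]
        p0 <- pos_tab$position0[i]
        al <- score_site(mid, mseq, tr, tseq[[tr]], ss[i], cpos, max_score)
        if (is.null(al)) next
        prof <- tplots[[tr]]$counts
        al$site_count <- prof[p0 + 1L]
        al$category <- categorize_site(prof, p0)
        calls[[length(calls) + 1L]] <- al
      }
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  # dedup (miRNA, transcript, cleavage position), keep best score
  key <- paste(out$mirna, out$transcript, out$cleavage_pos0, sep = "\r")
  out <- out[order(key, out$score), ]
  out <- out[!duplicated(paste(out$mirna, out$transcript, out$cleavage_pos0,
                               sep = "\r")), ]
  out <- out[order(out$category, out$score, out$mirna, out$transcript), ]
  rownames(out) <- NULL
  attr(out, "tplots") <- tplots
  out
}
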