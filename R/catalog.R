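#' Match reads against a mature miRNA reference with a mismatch budget
#'
#' Ungapped end-to-end comparison after aligning 5' ends. The distance is
#' the number of substitutions over the shared length plus the length
#' difference (unaligned overhang positions count toward the budget), which
#' makes it symmetric in read and reference. For each read the best
#' (lowest-distance) reference is reported; ties report all tied references.
#'
#' At pipeline scale a pigeonhole seed filter is applied first: three
#' disjoint 5-mers in the first 15 nt of the 5'-aligned pair; with at most
#' two substitutions at least one 5-mer is intact, so the filter is
#' lossless for `max_mismatch <= 2` (and is bypassed for larger budgets).
#'
#' @param reads character vector of read sequences, or collapsed-read
#'   data.frame.
#' @param reference data.frame `id`, `sequence` (mature miRNAs, 18-25 nt;
#'   RNA letters accepted).
#' @param max_mismatch total mismatch budget (default 2).
#' @return data.frame `sequence`, `ref_id`, `n_mismatch`.
#' @export
match_conserved <- function(reads, reference, max_mismatch = 2L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- unique(as_dna(toupper(reads)))
  refs <- as_dna(toupper(reference$sequence))
  stopifnot(all(nchar(refs) >= 16))
  empty <- data.frame(sequence = character(), ref_id = character(),
                      n_mismatch = integer(), stringsAsFactors = FALSE)
  if (!length(reads) || !nrow(reference)) return(empty)

  rlen <- nchar(reads)
  Llen <- nchar(refs)
  keep <- rlen >= min(Llen) - max_mismatch & rlen <= max(Llen) + max_mismatch
  reads_k <- reads[keep]
  if (!length(reads_k)) return(empty)

  chunk_starts <- c(1L, 6L, 11L)
  pairs <- if (max_mismatch <= 2L && all(nchar(reads_k) >= 15L)) {
    cand <- list()
    for (cs in chunk_starts) {
      rk <- substr(reads_k, cs, cs + 4L)
      fk <- substr(refs, cs, cs + 4L)
      grp <- split(seq_along(refs), fk)
      hit <- grp[rk]
      nh <- lengths(hit); nh[is.na(names(hit))] <- 0L
      ok <- which(nh > 0)
      if (length(ok)) {
        cand[[length(cand) + 1L]] <- data.frame(
          read = rep(ok, nh[ok]),
          ref = unlist(hit[ok], use.names = FALSE))
      }
    }
    if (!length(cand)) return(empty)
    unique(do.call(rbind, cand))
  } else {
    expand.grid(read = seq_along(reads_k), ref = seq_along(refs))
  }

  a <- reads_k[pairs$read]
  b <- refs[pairs$ref]
  la <- nchar(a); lb <- nchar(b)
  shared <- pmin(la, lb)
  overhang <- abs(la - lb)
  subs <- mapply(function(x, y, l) {
    sum(strsplit(substr(x, 1L, l), "", fixed = TRUE)[[1]] !=
          strsplit(substr(y, 1L, l), "", fixed = TRUE)[[1]])
  }, a, b, shared, USE.NAMES = FALSE)
  dist <- subs + overhang
  ok <- dist <= max_mismatch
  if (!any(ok)) return(empty)
  res <- data.frame(sequence = a[ok], ref_id = reference$id[pairs$ref[ok]],
                    n_mismatch = as.integer(dist[ok]),
                    stringsAsFactors = FALSE)
  # keep only best-distance hits per read (all ties)
  best <- tapply(res$n_mismatch, res$sequence, min)
  res <- res[res$n_mismatch == best[res$sequence], , drop = FALSE]
  res <- res[order(res$sequence, res$ref_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Excise candidate precursor windows around a mapped miRNA locus
#'
#' Two windows per locus, one with the mature near the window's 5' end and
#' one with it near the 3' end (flank on the opposite side), clipped at the
#' reference bounds and truncated (from the side away from the mature) to
#' at most `cap` nt.
#'
#' @param reference_seq reference sequence (DNA string).
#' @param start0,end0 0-based half-open locus of the mature on the forward
#'   strand.
#' @param strand `"+"` or `"-"`; for `"-"` the window sequence is reverse
#'   complemented so the mature reads 5' to 3'.
#' @param flank flanking length (nt) per side (default 250).
#' @param cap maximum window length (default 350 nt).
#' @param near_mature nt kept on the short side of the mature (default 20).
#' @return data.frame `window`, `start0`, `end0`, `sequence`,
#'   `mature_start0`, `mature_end0` (mature coordinates within the window).
#' @export
excise_precursors <- function(reference_seq, start0, end0, strand = "+",
                              flank = 250L, cap = 350L, near_mature = 20L) {
  len <- nchar(reference_seq)
  if (start0 < 0 || end0 > len || start0 >= end0) {
    stop("locus outside reference")
  }
  mk <- function(ws, we, anchor) {
    ws <- max(0L, ws); we <- min(len, we)
    if (we - ws > cap) {
      if (anchor == "5p") we <- ws + cap else ws <- we - cap
    }
    # never clip into the mature itself
    ws <- min(ws, start0); we <- max(we, end0)
    sq <- substr(reference_seq, ws + 1L, we)
    ms <- start0 - ws; me <- end0 - ws
    if (strand == "-") {
      sq <- revcomp(sq)
      w <- we - ws
      tmp <- w - me; me <- w - ms; ms <- tmp
    }
    data.frame(start0 = ws, end0 = we, sequence = sq,
               mature_start0 = ms, mature_end0 = me,
               stringsAsFactors = FALSE)
  }
  if (strand == "-") {
    # mature near window 5' end means flank on the forward-strand left
    w1 <- mk(start0 - flank, end0 + near_mature, "3p")
    w2 <- mk(start0 - near_mature, end0 + flank, "5p")
  } else {
    w1 <- mk(start0 - near_mature, end0 + flank, "5p")
    w2 <- mk(start0 - flank, end0 + near_mature, "3p")
  }
  out <- rbind(w1, w2)
  out <- cbind(window = c("mature_5p", "mature_3p"), out)
  out
}

#' Fold an RNA (or DNA) sequence into a nested secondary structure
#'
#' Dynamic programming maximising stacking-weighted base pairs (GC = 3,
#' AU = 2, GU = 1, plus 1 per stacked pair) with hairpin loops of at least
#' `min_loop` nt. The score is converted to a pseudo-energy estimate
#' (`-energy_scale` kcal/mol per score unit); these estimates are
#' deterministic and oracle-checkable but are not thermodynamic free
#' energies, so all downstream energy thresholds are configurable.
#'
#' @param sequence RNA or DNA string (no ambiguity codes).
#' @param min_loop minimum hairpin loop size (default 3).
#' @param energy_scale kcal/mol per score unit (default 0.4).
#' @return list `structure` (dot-bracket), `score`, `mfe_estimate`
#'   (kcal/mol, always <= 0).
#' @export
fold_rna <- function(sequence, min_loop = 3L, energy_scale = 0.4) {
  s <- as_dna(toupper(sequence))
  if (nchar(s) < 1) stop("empty sequence")
  if (grepl("[^ACGT]", s)) stop("sequence contains non-RNA letters")
  res <- .fold_cpp(s, as.integer(min_loop))
  list(structure = res$structure, score = res$score,
       mfe_estimate = -energy_scale * res$score)
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector; position `i` holds the 1-based partner of base
#'   `i`, or 0 if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure")
  pt
}

#' Expected miRNA* sequence from a folded precursor
#'
#' The star is the partner strand of the mature in the precursor duplex,
#' shifted so both duplex ends carry 2-nt 3' overhangs. Anchors fall back
#' to the nearest paired mature base when the canonical anchor positions
#' are unpaired. A mature spanning the hairpin loop is an error.
#'
#' @param precursor precursor sequence (DNA/RNA string).
#' @param structure dot-bracket structure of the precursor.
#' @param mature_start0,mature_end0 0-based half-open mature coordinates
#'   within the precursor.
#' @param reads optional collapsed-read data.frame; when given, the star is
#'   flagged `observed` if its sequence occurs with count >= 1.
#' @return list `star` (sequence), `star_start0`, `star_end0`, `observed`
#'   (logical, `NA` when no reads supplied).
#' @export
find_star <- function(precursor, structure, mature_start0, mature_end0,
                      reads = NULL) {
  precursor <- as_dna(toupper(precursor))
  pt <- pair_table(structure)
  ms <- mature_start0 + 1L
  me <- mature_end0            # 1-based inclusive
  n <- nchar(precursor)
  stopifnot(ms >= 1, me <= n, ms < me)
  part <- pt[ms:me]
  inside <- part >= ms & part <= me
  if (any(inside & part > 0)) stop("mature_in_loop")
  if (all(part == 0)) stop("mature_unpaired")
  # anchor near the mature 3' end (position me - 2)
  k3 <- me - 2L
  while (k3 >= ms && pt[k3] == 0) k3 <- k3 - 1L
  # anchor near the mature 5' end
  k5 <- ms
  while (k5 <= me && pt[k5] == 0) k5 <- k5 + 1L
  if (k3 < ms || k5 > me) stop("mature_unpaired")
  star_start <- pt[k3] - ((me - 2L) - k3)
  star_end <- pt[k5] + (k5 - ms) + 2L
  star_start <- max(1L, star_start)
  star_end <- min(n, star_end)
  if (star_start >= star_end) stop("star_undefined")
  star <- substr(precursor, star_start, star_end)
  observed <- NA
  if (!is.null(reads)) {
    libs <- .lib_cols(reads)
    tot <- rowSums(reads[, libs, drop = FALSE])
    observed <- star %in% reads$sequence[tot >= 1]
  }
  list(star = star, star_start0 = star_start - 1L, star_end0 = star_end,
       observed = observed)
}

#' Evaluate a hairpin candidate against plant miRNA annotation criteria
#'
#' Pass requires all of: mature and star on opposite arms of a single
#' stem-loop; at most `max_duplex_mismatch` unpaired mature positions in
#' the mature/star duplex; total asymmetric bulge within the duplex at most
#' `max_asym_bulge` nt; a star definable by the 2-nt 3' overhang rule; a
#' folding energy estimate at or below `mfe_threshold`; and precursor
#' length within `precursor_length`. Reason codes list every failed
#' criterion.
#'
#' @param precursor precursor sequence (DNA/RNA string).
#' @param mature_start0,mature_end0 0-based half-open mature coordinates.
#' @param reads optional collapsed reads for star observation.
#' @param structure,mfe_estimate optional precomputed fold; folded on the
#'   fly when missing.
#' @param max_duplex_mismatch default 4.
#' @param max_asym_bulge default 2 nt.
#' @param mfe_threshold default -18 kcal/mol (on the pseudo-energy scale).
#' @param precursor_length allowed length range, default c(60, 350).
#' @return list `pass`, `reasons`, `duplex_mismatches`, `asymmetric_bulge_nt`,
#'   `star` (from [find_star()], or `NULL`), `structure`, `mfe_estimate`.
#' @export
check_meyers <- function(precursor, mature_start0, mature_end0, reads = NULL,
                         structure = NULL, mfe_estimate = NULL,
                         max_duplex_mismatch = 4L, max_asym_bulge = 2L,
                         mfe_threshold = -18, precursor_length = c(60L, 350L)) {
  precursor <- as_dna(toupper(precursor))
  n <- nchar(precursor)
  if (is.null(structure) || is.null(mfe_estimate)) {
    f <- fold_rna(precursor)
    structure <- f$structure
    mfe_estimate <- f$mfe_estimate
  }
  reasons <- character(0)
  if (n < precursor_length[1] || n > precursor_length[2]) {
    reasons <- c(reasons, "precursor_length")
  }
  if (mfe_estimate > mfe_threshold) reasons <- c(reasons, "mfe")

  star <- tryCatch(
    find_star(precursor, structure, mature_start0, mature_end0, reads),
    error = function(e) conditionMessage(e))
  dm <- NA_integer_; asym <- NA_integer_
  if (is.character(star)) {
    reasons <- c(reasons, if (star %in% c("mature_in_loop", "mature_unpaired",
                                          "star_undefined")) star
                 else "star_undefined")
    star <- NULL
  } else {
    pt <- pair_table(structure)
    ms <- mature_start0 + 1L; me <- mature_end0
    ss <- star$star_start0 + 1L; se <- star$star_end0
    part <- pt[ms:me]
    # paired to the opposite arm (anywhere outside the mature itself)
    in_star <- part > 0 & !(part >= ms & part <= me)
    dm <- sum(!in_star)
    if (dm > max_duplex_mismatch) reasons <- c(reasons, "duplex_mismatches")
    paired_pos <- (ms:me)[in_star]
    if (length(paired_pos) >= 2) {
      partners <- pt[paired_pos]
      if (any(diff(partners) >= 0)) {
        reasons <- c(reasons, "arm_structure")   # partners must descend: single helix
        asym <- NA_integer_
      } else {
        gaps_m <- diff(paired_pos) - 1L
        gaps_s <- -diff(partners) - 1L
        asym <- sum(abs(gaps_m - gaps_s))
        if (asym > max_asym_bulge) reasons <- c(reasons, "asymmetric_bulge")
      }
    } else if (dm <= max_duplex_mismatch) {
      reasons <- c(reasons, "arm_structure")
    }
    # star and mature must not overlap (opposite arms)
    if (max(ms, ss) <= min(me, se)) reasons <- c(reasons, "arm_structure")
  }
  reasons <- unique(reasons)
  list(pass = length(reasons) == 0, reasons = reasons,
       duplex_mismatches = dm, asymmetric_bulge_nt = asym, star = star,
       structure = structure, mfe_estimate = mfe_estimate)
}

#' Discover novel miRNA candidates from unannotated reads
#'
#' For each unannotated read that maps perfectly onto the transcript
#' reference, candidate precursor windows are excised, folded, and checked
#' against the stem-loop annotation criteria; a read passes if any window
#' does. Candidates are deduplicated by precursor locus.
#'
#' Candidates are processed in the given order (callers usually sort by
#' abundance); once a candidate is accepted, its whole precursor window is
#' consumed, so star and isomiR reads of an accepted locus do not spawn
#' additional loci. Loci of `exclude_seqs` (e.g. reads already matched to
#' the conserved reference) are consumed up front with a `cap`-sized
#' exclusion zone.
#'
#' @param collapsed collapsed reads (all libraries).
#' @param candidate_seqs character vector of unannotated read sequences to
#'   consider (18-25 nt enforced), in priority order.
#' @param transcripts reference data.frame `id`, `sequence`.
#' @param exclude_seqs sequences whose mapped loci are excluded from
#'   discovery (known-miRNA reads).
#' @param flank,cap see [excise_precursors()].
#' @param ... passed to [check_meyers()].
#' @return data.frame: `id`, `sequence`, `arm`, `ref`, `start0`, `end0`,
#'   `strand`, `precursor`, `structure`, `mfe_estimate`, `star`,
#'   `star_observed`, plus per-library counts.
#' @export
discover_novel <- function(collapsed, candidate_seqs, transcripts,
                           exclude_seqs = character(0),
                           flank = 250L, cap = 350L, ...) {
  candidate_seqs <- unique(as_dna(toupper(candidate_seqs)))
  candidate_seqs <- candidate_seqs[nchar(candidate_seqs) >= 18 &
                                     nchar(candidate_seqs) <= 25]
  libs <- .lib_cols(collapsed)
  empty <- data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (!length(candidate_seqs)) return(empty)
  hits <- map_perfect(candidate_seqs, transcripts)
  if (!nrow(hits)) return(empty)
  hits <- hits[order(match(hits$sequence, candidate_seqs)), , drop = FALSE]
  consumed <- data.frame(ref = character(), lo = integer(), hi = integer(),
                         stringsAsFactors = FALSE)
  if (length(exclude_seqs)) {
    ex <- map_perfect(unique(as_dna(toupper(exclude_seqs))), transcripts)
    if (nrow(ex)) {
      consumed <- data.frame(ref = ex$ref, lo = ex$start0 - cap,
                             hi = ex$end0 + cap, stringsAsFactors = FALSE)
    }
  }
  overlaps <- function(ref, s, e) {
    any(consumed$ref == ref & consumed$lo < e & consumed$hi > s)
  }
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (overlaps(h$ref, h$start0, h$end0)) next
    tseq <- transcripts$sequence[transcripts$id == h$ref]
    wins <- excise_precursors(tseq, h$start0, h$end0, h$strand,
                              flank = flank, cap = cap)
    for (w in seq_len(nrow(wins))) {
      win <- wins[w, ]
      verdict <- check_meyers(win$sequence, win$mature_start0,
                              win$mature_end0, reads = collapsed, ...)
      if (verdict$pass) {
        cnt <- collapsed[match(h$sequence, collapsed$sequence), libs,
                         drop = FALSE]
        if (nrow(cnt) == 0 || anyNA(cnt)) {
          cnt <- as.data.frame(as.list(stats::setNames(
            integer(length(libs)), libs)))
        }
        arm <- if (win$mature_start0 <
                   nchar(win$sequence) - win$mature_end0) "5p" else "3p"
        rows[[length(rows) + 1L]] <- cbind(data.frame(
          id = "", sequence = h$sequence, arm = arm, ref = h$ref,
          start0 = h$start0, end0 = h$end0, strand = h$strand,
          precursor = win$sequence, structure = verdict$structure,
          mfe_estimate = verdict$mfe_estimate,
          star = verdict$star$star,
          star_observed = isTRUE(verdict$star$observed),
          stringsAsFactors = FALSE), cnt)
        consumed <- rbind(consumed, data.frame(
          ref = h$ref, lo = win$start0, hi = win$end0,
          stringsAsFactors = FALSE))
        break
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$id <- sprintf("novel-mir%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson style shuffle: permutes the edges of the dinucleotide
#' multigraph so the shuffled sequence keeps the exact dinucleotide
#' composition. Used for negative-control precursors.
#'
#' @param sequence DNA/RNA string.
#' @return shuffled sequence (same alphabet as input, DNA internally).
#' @export
shuffle_dinucleotide <- function(sequence) {
  s <- strsplit(as_dna(toupper(sequence)), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 3) return(paste(s, collapse = ""))
  # edge lists of the dinucleotide multigraph
  edges <- split(s[-1], s[-n])
  last <- s[n]
  repeat {
    sh <- lapply(edges, sample)
    # walk the graph; accept if all edges are consumed (valid Euler path)
    ptr <- stats::setNames(rep(1L, length(sh)), names(sh))
    out <- character(n)
    out[1] <- s[1]
    ok <- TRUE
    for (i in 2:n) {
      v <- out[i - 1]
      lst <- sh[[v]]
      if (is.null(lst) || ptr[v] > length(lst)) { ok <- FALSE; break }
      out[i] <- lst[ptr[v]]
      ptr[v] <- ptr[v] + 1L
    }
    if (ok && out[n] == last) return(paste(out, collapse = ""))
    if (ok) return(paste(out, collapse = ""))  # same multiset; accept
  }
}

#' Exhaustive folding oracle by structure enumeration
#'
#' Enumerates every nested structure (vectorised over structure counts) and
#' returns the maximum stacking-weighted score, for validating [fold_rna()]
#' on short sequences. Independent of the dynamic-programming fill: regions
#' are decomposed by the leftmost position's pairing status and all
#' combinations are expanded.
#'
#' @param sequence DNA/RNA string (intended for <= 25 nt).
#' @param min_loop minimum hairpin loop size (default 3).
#' @return list `score` (maximum), `n_structures` (number enumerated).
#' @export
fold_exhaustive <- function(sequence, min_loop = 3L) {
  s <- strsplit(as_dna(toupper(sequence)), "", fixed = TRUE)[[1]]
  n <- length(s)
  w <- function(a, b) {
    k <- paste0(s[a], s[b])
    switch(k, GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1, -Inf)
  }
  memo <- new.env(parent = emptyenv())
  # returns list(scores, endpair): one entry per structure of region [i, j]
  enum <- function(i, j) {
    if (j - i + 1 < 2) return(list(scores = 0, endpair = FALSE))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    sc <- numeric(0); ep <- logical(0)
    sub <- enum(i + 1, j)                       # i unpaired
    sc <- c(sc, sub$scores); ep <- c(ep, rep(FALSE, length(sub$scores)))
    for (k in seq.int(i + min_loop + 1, j, length.out = max(0, j - i - min_loop))) {
      wk <- w(i, k)
      if (!is.finite(wk)) next
      inner <- enum(i + 1, k - 1)
      left <- wk + inner$scores +
        ifelse(inner$endpair & (k - 1) - (i + 1) + 1 >= 2, 1, 0)
      if (k < j) {
        right <- enum(k + 1, j)
        comb <- as.vector(outer(left, right$scores, `+`))
        sc <- c(sc, comb); ep <- c(ep, rep(FALSE, length(comb)))
      } else {
        sc <- c(sc, left); ep <- c(ep, rep(TRUE, length(left)))
      }
    }
    res <- list(scores = sc, endpair = ep)
    memo[[key]] <- res
    res
  }
  all_s <- enum(1, n)
  list(score = max(all_s$scores), n_structures = length(all_s$scores))
}
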