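#' Reads-per-million normalisation
#'
#' `count / total * 1e6`, with no pseudo-count.
#'
#' @param count miRNA read count (non-negative).
#' @param total library total clean reads (> 0).
#' @return normalised expression (RPM).
#' @export
normalize_rpm <- function(count, total) {
  stopifnot(all(total > 0), all(count >= 0))
  count / total * 1e6
}

#' Log2 fold change between two normalised expression values
#'
#' `log2(norm2 / norm1)`: in a comparison written "A/B", B is the baseline
#' (denominator, `norm1`) and the fold change is positive when A is higher.
#'
#' @param norm1 baseline (denominator) RPM, > 0.
#' @param norm2 numerator RPM, > 0.
#' @return log2 ratio.
#' @export
fold_change <- function(norm1, norm2) {
  stopifnot(all(norm1 > 0), all(norm2 > 0))
  log2(norm2 / norm1)
}

#' Exact test for a count pair under proportional sampling
#'
#' The probability of observing count `y` in a library of `n2` total clean
#' reads given count `x` in a library of `n1` totals,
#' `p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1))` with `r = n2/n1`,
#' summed into a lower tail `C = sum(p(y'|x), y' <= y)` and an upper tail
#' `D = 1 - C(y-1)` (no infinite summation). Terms are computed in
#' log-space via `lgamma`. The two-sided P-value is `min(1, 2 min(C, D))`.
#'
#' @param x count in library 1 (the baseline whose total is `n1`).
#' @param y count in library 2.
#' @param n1,n2 total clean reads in libraries 1 and 2 (> 0).
#' @return list `C`, `D`, `p` (two-sided).
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  if (x < 0 || y < 0 || n1 <= 0 || n2 <= 0) stop("negative or zero inputs")
  logr <- log(n2) - log(n1)
  log1pr <- log1p(n2 / n1)
  lterm <- function(yy) {
    yy * logr + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
      (x + yy + 1) * log1pr
  }
  cum <- function(upto) {
    if (upto < 0) return(0)
    sum(exp(lterm(0:upto)))
  }
  C <- min(1, cum(y))
  low <- if (y >= 1) cum(y - 1) else 0
  if (low <= 0.5) {
    D <- min(1, 1 - low)
  } else {
    # the upper tail is small: 1 - low loses precision, so sum the tail
    # directly in finite blocks until the geometric decay makes further
    # terms negligible
    D <- 0
    yy <- y
    repeat {
      block <- exp(lterm(yy:(yy + 255)))
      D <- D + sum(block)
      yy <- yy + 256
      if (block[256] < D * 1e-17 + 1e-300) break
    }
    D <- min(1, D)
  }
  list(C = C, D = D, p = min(1, 2 * min(C, D)))
}

#' Classify a differential-expression result
#'
#' The low-expression rule: a miRNA below `min_rpm` in both libraries is
#' `filtered`; if exactly one side is below, that side is floored at
#' `min_rpm` before the fold change (keeping it finite). Then `up` requires
#' `log2fc >= fc_threshold` and `p <= p_threshold`, `down` the mirror
#' image, otherwise `ns`. With `floor_single = FALSE` any side below
#' `min_rpm` filters the miRNA instead.
#'
#' @param rpm1 baseline RPM; @param rpm2 numerator RPM.
#' @param pvalue two-sided exact-test P-value.
#' @param fc_threshold absolute log2 fold-change threshold (default 1).
#' @param p_threshold P-value threshold (default 0.05).
#' @param min_rpm low-expression floor (default 1 RPM).
#' @param floor_single floor a single low side rather than filter?
#' @return list `status` (up/down/ns/filtered), `log2fc` (`NA` when
#'   filtered), `rpm1`, `rpm2` (after flooring).
#' @export
classify_de <- function(rpm1, rpm2, pvalue, fc_threshold = 1.0,
                        p_threshold = 0.05, min_rpm = 1.0,
                        floor_single = TRUE) {
  low1 <- rpm1 < min_rpm
  low2 <- rpm2 < min_rpm
  if ((low1 && low2) || ((low1 || low2) && !floor_single)) {
    return(list(status = "filtered", log2fc = NA_real_,
                rpm1 = rpm1, rpm2 = rpm2))
  }
  if (low1) rpm1 <- min_rpm
  if (low2) rpm2 <- min_rpm
  lfc <- fold_change(rpm1, rpm2)
  status <- if (pvalue <= p_threshold && lfc >= fc_threshold) "up"
  else if (pvalue <= p_threshold && lfc <= -fc_threshold) "down"
  else "ns"
  list(status = status, log2fc = lfc, rpm1 = rpm1, rpm2 = rpm2)
}

#' Differential expression for one library pair
#'
#' Runs normalisation, the exact test and classification for every miRNA in
#' the matrix for a pair written `"A/B"` (B = baseline). Results are in the
#' matrix's row order (deterministic).
#'
#' @param counts integer matrix (rows = miRNA ids, columns = libraries).
#' @param totals named vector of library total clean reads.
#' @param pair comparison string, e.g. `"PF2S/PF2U"`.
#' @param p_adjust multiple-testing adjustment passed to [stats::p.adjust()];
#'   default `"none"` (raw P-values thresholded).
#' @param ... thresholds passed to [classify_de()].
#' @return data.frame `id`, `count1`, `count2`, `rpm1`, `rpm2`, `log2fc`,
#'   `pvalue`, `status`, with attributes `n_up` / `n_down`.
#' @export
compare_libraries <- function(counts, totals, pair, p_adjust = "none", ...) {
  libs <- strsplit(pair, "/", fixed = TRUE)[[1]]
  if (length(libs) != 2 || !all(libs %in% colnames(counts)) ||
      !all(libs %in% names(totals))) {
    stop(sprintf("pair '%s' references unknown libraries", pair))
  }
  num <- libs[1]; den <- libs[2]
  n <- nrow(counts)
  out <- data.frame(id = if (is.null(rownames(counts))) character(n)
                    else rownames(counts),
                    count1 = counts[, den], count2 = counts[, num],
                    rpm1 = normalize_rpm(counts[, den], totals[[den]]),
                    rpm2 = normalize_rpm(counts[, num], totals[[num]]),
                    log2fc = rep(NA_real_, n), pvalue = rep(NA_real_, n),
                    status = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n > 0) {
    for (i in seq_len(n)) {
      out$pvalue[i] <- ac_pvalue(out$count1[i], out$count2[i],
                                 totals[[den]], totals[[num]])$p
    }
    out$pvalue <- stats::p.adjust(out$pvalue, method = p_adjust)
    for (i in seq_len(n)) {
      cl <- classify_de(out$rpm1[i], out$rpm2[i], out$pvalue[i], ...)
      out$status[i] <- cl$status
      out$log2fc[i] <- cl$log2fc
    }
  }
  rownames(out) <- NULL
  attr(out, "pair") <- pair
  attr(out, "n_up") <- sum(out$status == "up")
  attr(out, "n_down") <- sum(out$status == "down")
  out
}

#' Salt-associated miRNA set logic over the four comparisons
#'
#' `salt_responsive`: significant (up or down) in both the diploid
#' (2S/2U) and tetraploid (4S/4U) salt comparisons. `cross_ploidy`: also
#' significant in the 4S/2S comparison. `tolerance_candidates`:
#' cross-ploidy miRNAs minus those with the same up/down status in the
#' 4S/2S and 4U/2U comparisons (removing ploidy-difference effects).
#'
#' @param de_2S2U,de_4S4U,de_4S2S,de_4U2U comparison results from
#'   [compare_libraries()] over the same miRNA universe.
#' @return list of character vectors `salt_responsive`, `cross_ploidy`,
#'   `tolerance_candidates`.
#' @export
salt_associated <- function(de_2S2U, de_4S4U, de_4S2S, de_4U2U) {
  sig <- function(de) de$id[de$status %in% c("up", "down")]
  status_of <- function(de, ids) de$status[match(ids, de$id)]
  salt <- intersect(sig(de_2S2U), sig(de_4S4U))
  cross <- intersect(salt, sig(de_4S2S))
  same_trend <- cross[status_of(de_4S2S, cross) == status_of(de_4U2U, cross)]
  list(salt_responsive = salt, cross_ploidy = cross,
       tolerance_candidates = setdiff(cross, same_trend))
}

#' Relative expression by the 2^-ddCt method
#'
#' Triplicate Ct values are averaged first; then
#' `ddCt = (Ct_target - Ct_ref)_treated - (Ct_target - Ct_ref)_control`
#' and the relative expression is `2^-ddCt`.
#'
#' @param ct data.frame with columns `gene` (`target`/`reference`),
#'   `condition` (`treated`/`control`) and `ct` (cycle thresholds, > 0), or
#'   a numeric vector `c(target_treated, ref_treated, target_control,
#'   ref_control)` of already-averaged Ct values.
#' @return list `ddct`, `relative_expression`.
#' @export
ddct <- function(ct) {
  if (is.numeric(ct)) {
    stopifnot(length(ct) == 4, all(ct > 0))
    m <- ct
  } else {
    stopifnot(all(ct$ct > 0))
    key <- paste(ct$gene, ct$condition, sep = ".")
    avg <- tapply(ct$ct, key, mean)
    need <- c("target.treated", "reference.treated",
              "target.control", "reference.control")
    if (!all(need %in% names(avg))) {
      stop("ct table must cover target/reference x treated/control")
    }
    m <- as.numeric(avg[need])
  }
  dd <- (m[1] - m[2]) - (m[3] - m[4])
  list(ddct = dd, relative_expression = 2^(-dd))
}

#' Build a miRNA expression matrix from collapsed reads and catalog hits
#'
#' Counts per miRNA id and library: the sum of collapsed counts of all
#' reads assigned to that id. A read tied between several best references
#' contributes to each of them (ties are rare for distinct references and
#' are reported by [match_conserved()]).
#'
#' @param collapsed collapsed-read data.frame covering all libraries.
#' @param assignments data.frame `sequence`, `ref_id` (e.g. from
#'   [match_conserved()]).
#' @return integer matrix, rows = miRNA ids, columns = libraries.
#' @export
expression_matrix <- function(collapsed, assignments) {
  libs <- .lib_cols(collapsed)
  ids <- sort(unique(assignments$ref_id))
  mat <- matrix(0L, nrow = length(ids), ncol = length(libs),
                dimnames = list(ids, libs))
  idx <- match(assignments$sequence, collapsed$sequence)
  ok <- !is.na(idx)
  for (l in libs) {
    v <- tapply(collapsed[[l]][idx[ok]], assignments$ref_id[ok], sum)
    mat[names(v), l] <- as.integer(v)
  }
  mat
}
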