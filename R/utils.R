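#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over the internal DNA alphabet. `U` is
#' treated as `T` (complement `A`); `N` maps to `N`.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUN", "TGCAAN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Convert between RNA and DNA alphabets
#'
#' The package works internally in DNA space (`U` converted to `T` on
#' ingest); RNA letters are emitted only in reports.
#'
#' @param x character vector of sequences.
#' @return converted character vector.
#' @export
as_dna <- function(x) chartr("Uu", "Tt", x)

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

#' Round half away from zero
#'
#' Rounding rule used for printed percentages in annotation summaries
#' (base R `round` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# deterministic 31-bit hash of a string, for artifact-keyed RNG streams
.string_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (k in v) h <- (h * 131 + k) %% 2147483629
  as.integer(h)
}

# Each simulated artifact draws from its own stream keyed by (seed, name),
# so adding one output never perturbs the others.
with_artifact_seed <- function(seed, name, expr) {
  s <- (as.integer(seed) %% 1000003L) * 2029L + .string_hash(name)
  s <- as.integer(s %% 2147483629)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(s)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# short stable hash of an R object (for parameter provenance headers)
.param_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", .string_hash(s))
}

# split sequences into a padded character matrix (NA beyond each length)
.seq_matrix <- function(seqs, width = max(nchar(seqs))) {
  n <- length(seqs)
  mat <- matrix(NA_character_, nrow = n, ncol = width)
  sp <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_len(n)) {
    ch <- sp[[i]]
    if (length(ch) > width) ch <- ch[seq_len(width)]
    mat[i, seq_along(ch)] <- ch
  }
  mat
}

# write a TSV with a provenance comment line; stable column order
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
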