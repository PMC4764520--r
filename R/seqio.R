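#' Read a FASTA file
#'
#' Sequences are uppercased on read; RNA letters (`U`) are preserved so that
#' miRBase-style mature references can be round-tripped. Multi-line records
#' are concatenated. Malformed input raises an error naming the offending
#' line.
#'
#' @param path path to a FASTA file (plain text or gzip).
#' @return data.frame with columns `id`, `sequence`, `quality` (all `NA` for
#'   FASTA input).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA parse error at line 1: expected '>' header")
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  buf <- character(0)
  hdr_line <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    s <- toupper(paste(buf, collapse = ""))
    if (nchar(s) == 0) {
      stop(sprintf("FASTA parse error at line %d: record '%s' has empty sequence",
                   hdr_line, cur))
    }
    if (grepl("[^ACGTUN]", s)) {
      stop(sprintf("FASTA parse error near line %d: invalid letters in record '%s'",
                   hdr_line, cur))
    }
    ids[length(ids) + 1L] <<- cur
    seqs[length(seqs) + 1L] <<- s
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush()
      cur <- sub("^>\\s*", "", ln)
      cur <- sub("\\s.*$", "", cur)
      if (nchar(cur) == 0) {
        stop(sprintf("FASTA parse error at line %d: empty header", i))
      }
      hdr_line <- i
      buf <- character(0)
    } else {
      if (is.null(cur)) {
        stop(sprintf("FASTA parse error at line %d: sequence before header", i))
      }
      buf[length(buf) + 1L] <- gsub("\\s", "", ln)
    }
  }
  flush()
  data.frame(id = ids, sequence = seqs, quality = NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a FASTQ file (Phred+33)
#'
#' Strict four-line records. A quality string whose length differs from its
#' sequence raises a parse error naming the record's line number.
#'
#' @param path path to a FASTQ file (plain text or gzip).
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop(sprintf("FASTQ parse error: %d lines is not a multiple of 4",
                 length(lines)))
  }
  n <- length(lines) / 4
  if (n == 0) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  at <- function(k) lines[seq.int(k, by = 4, length.out = n)]
  hdr <- at(1); seq <- toupper(at(2)); plus <- at(3); qual <- at(4)
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop(sprintf("FASTQ parse error at line %d: expected '@' header",
                 (bad[1] - 1) * 4 + 1))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("FASTQ parse error at line %d: expected '+' separator",
                 (bad[1] - 1) * 4 + 3))
  }
  bad <- which(nchar(qual) != nchar(seq))
  if (length(bad)) {
    stop(sprintf(
      "FASTQ parse error at line %d: quality length %d != sequence length %d",
      (bad[1] - 1) * 4 + 4, nchar(qual[bad[1]]), nchar(seq[bad[1]])))
  }
  bad <- which(grepl("[^ACGTUN]", seq))
  if (length(bad)) {
    stop(sprintf("FASTQ parse error at line %d: invalid letters",
                 (bad[1] - 1) * 4 + 2))
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             sequence = seq, quality = qual, stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with `id` and `sequence`.
#' @param path output path.
#' @param rna emit RNA letters (T converted to U)?
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, rna = FALSE) {
  seqs <- records$sequence
  if (rna) seqs <- as_rna(seqs)
  writeLines(paste0(">", records$id, "\n", seqs), path, sep = "\n")
  invisible(path)
}

#' Write sequence records to FASTQ (Phred+33)
#'
#' @param records data.frame with `id`, `sequence`, `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(nchar(records$quality) == nchar(records$sequence)))
  writeLines(paste0("@", records$id, "\n", records$sequence, "\n+\n",
                    records$quality), path, sep = "\n")
  invisible(path)
}

.lib_cols <- function(collapsed) setdiff(names(collapsed), "sequence")

#' Write collapsed reads in the `seqN_xCOUNT` FASTA dialect
#'
#' One record per unique sequence with that library's count embedded in the
#' header (`>seq1_x42`). Reads with a zero count in the library are omitted;
#' output order is descending count, ties broken lexicographically by
#' sequence, so the file is deterministic.
#'
#' @param collapsed collapsed-read data.frame (`sequence` plus one count
#'   column per library).
#' @param library library id (must be a count column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, library, path) {
  if (!library %in% .lib_cols(collapsed)) {
    stop(sprintf("unknown library id '%s'", library))
  }
  cnt <- collapsed[[library]]
  keep <- which(cnt > 0)
  sq <- collapsed$sequence[keep]
  cnt <- cnt[keep]
  o <- order(-cnt, sq)
  sq <- sq[o]; cnt <- cnt[o]
  writeLines(if (length(sq)) {
    paste0(">seq", seq_along(sq), "_x", cnt, "\n", sq)
  } else character(0), path, sep = "\n")
  invisible(path)
}

#' Read a collapsed-read FASTA
#'
#' Parses the `_xCOUNT` header dialect; headers without a count suffix are
#' taken as count 1.
#'
#' @param path input path.
#' @param library library id to attach the counts to.
#' @return collapsed-read data.frame with columns `sequence` and `library`.
#' @export
read_collapsed_fasta <- function(path, library = "L1") {
  fa <- read_fasta(path)
  cnt <- rep(1L, nrow(fa))
  has <- grepl("_x\\d+$", fa$id)
  cnt[has] <- as.integer(sub("^.*_x(\\d+)$", "\\1", fa$id[has]))
  out <- data.frame(sequence = as_dna(fa$sequence), stringsAsFactors = FALSE)
  out[[library]] <- cnt
  # merge duplicate sequences, if any
  if (anyDuplicated(out$sequence)) {
    agg <- tapply(out[[library]], out$sequence, sum)
    out <- data.frame(sequence = names(agg), stringsAsFactors = FALSE)
    out[[library]] <- as.integer(unname(agg))
  }
  out
}

#' Merge per-library collapsed reads into one table
#'
#' Full outer join on sequence; missing counts become 0.
#'
#' @param collapsed_list named list of collapsed-read data.frames (each with
#'   a single library column).
#' @return collapsed-read data.frame with one count column per library.
#' @export
merge_collapsed <- function(collapsed_list) {
  seqs <- unique(unlist(lapply(collapsed_list, `[[`, "sequence"),
                        use.names = FALSE))
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (df in collapsed_list) {
    lib <- .lib_cols(df)
    for (l in lib) {
      v <- integer(length(seqs))
      v[match(df$sequence, seqs)] <- df[[l]]
      out[[l]] <- v
    }
  }
  out
}
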