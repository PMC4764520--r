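adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("clean_reads trims exact adapters and applies the length filters", {
  insert21 <- "ACGTACGTACGTACGTACGTA"
  insert17 <- "ACGTACGTACGTACGTA"
  reads <- make_records(
    c(paste0(insert21, adapter), paste0(insert17, adapter)),
    quals = c(strrep("I", 21 + nchar(adapter)),
              strrep("I", 17 + nchar(adapter))))
  out <- clean_reads(reads, cleaning_params(adapter3 = adapter))
  expect_equal(out$records$sequence, insert21)
  expect_equal(unname(out$stats["too_short"]), 1L)
  expect_equal(unname(out$stats["adapter_trimmed"]), 2L)
})

test_that("clean_reads tolerates adapter mismatches up to the budget", {
  insert <- "GATTACAGATTACAGATTACA"
  adap1 <- sub("^T", "A", adapter)   # one mismatch
  adap2 <- sub("^TG", "AC", adapter) # two mismatches
  reads <- make_records(c(paste0(insert, adap1), paste0(insert, adap2)))
  out <- clean_reads(reads, cleaning_params(adapter3 = adapter,
                                            max_adapter_mismatch = 1))
  # 1-mismatch adapter trimmed; 2-mismatch adapter not found -> read kept
  # untrimmed and dropped as too long
  expect_equal(out$records$sequence, insert)
  expect_equal(unname(out$stats["too_long"]), 1L)
})

test_that("clean_reads removes poly-A, N-containing and low-quality reads", {
  reads <- make_records(
    c(strrep("A", 21), "ACGTNCGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
      "ACGTACGTACGTACGTACGTA"),
    quals = c(strrep("I", 21), strrep("I", 21), strrep("#", 21),
              strrep("I", 21)))
  out <- clean_reads(reads, cleaning_params(adapter3 = adapter,
                                            polyA_fraction = 0.9))
  expect_equal(nrow(out$records), 1L)
  expect_equal(unname(out$stats[c("polyA", "ambiguous", "low_quality")]),
               c(1L, 1L, 1L))
  # conservation: input = retained + all removals
  expect_equal(unname(out$stats["input"]),
               unname(out$stats["retained"] + sum(out$stats[
                 c("too_short", "too_long", "low_quality", "ambiguous",
                   "polyA")])))
})

test_that("empty input yields empty output and zeroed stats", {
  out <- clean_reads(make_records(character(0)))
  expect_equal(nrow(out$records), 0L)
  expect_true(all(out$stats == 0))
})

test_that("collapse preserves total counts and multiplicities", {
  recs <- make_records(c("ACGT", "ACGT", "AAAA"))
  col <- collapse_reads(recs, "L1")
  expect_equal(col$L1[col$sequence == "ACGT"], 2L)
  expect_equal(col$L1[col$sequence == "AAAA"], 1L)

  expect_equal(nrow(collapse_reads(make_records(character(0)), "L1")), 0L)

  many <- make_records(rep("TTTTGGGGCCCCAAAA", 1000))
  colm <- collapse_reads(many, "L1")
  expect_equal(nrow(colm), 1L)
  expect_equal(sum(colm$L1), 1000L)
})

test_that("length_distribution: fractions sum to 1, zero lengths omitted", {
  col <- data.frame(sequence = c(strrep("A", 21), strrep("C", 21),
                                 strrep("G", 24)),
                    L1 = c(2L, 1L, 1L), stringsAsFactors = FALSE)
  ld <- length_distribution(col, "L1")
  expect_equal(ld$length, c(21L, 24L))
  expect_equal(ld$fraction, c(0.75, 0.25))
  expect_equal(sum(ld$fraction), 1, tolerance = 1e-12)

  one <- data.frame(sequence = strrep("A", 20), L1 = 5L)
  expect_equal(length_distribution(one, "L1")$fraction, 1.0)
})

test_that("map_perfect reports all exact hits on both strands, 0-based", {
  ref <- data.frame(id = "t1",
                    sequence = paste0(strrep("C", 10),
                                      "ACGTACGTACGTACGTACGTA",
                                      strrep("G", 10)),
                    stringsAsFactors = FALSE)
  hit <- map_perfect("ACGTACGTACGTACGTACGTA", ref)
  expect_equal(hit$start0, 10L)
  expect_equal(hit$strand, "+")

  rc <- revcomp(substr(ref$sequence, 1, 21))
  hit2 <- map_perfect(rc, ref)
  expect_true(any(hit2$start0 == 0L & hit2$strand == "-"))

  expect_equal(nrow(map_perfect("TTTTTTTTTTTTTTTTTTTTT", ref)), 0L)
})

test_that("classify_reads applies the fixed precedence and is total", {
  shared <- "ACGTACGTACGTACGTACGTAT"
  refs <- list(rRNA = data.frame(id = "r1", sequence = shared),
               tRNA = data.frame(id = "t1", sequence = shared))
  cls <- classify_reads(c(shared, "GGGGGGGGGGGGGGGGGGGG"), refs)
  expect_equal(unname(cls[shared]), "rRNA")       # rRNA beats tRNA
  expect_equal(unname(cls[2]), "unannotated")

  cls2 <- classify_reads(shared, refs, mirna_hits = shared)
  expect_equal(unname(cls2[shared]), "miRNA")     # miRNA beats everything
})

test_that("summarize_annotation sums exactly and rounds percentages", {
  col <- data.frame(sequence = c("AAAACCCCGGGGTTTTAC", "CCCCGGGGTTTTAAAAGT",
                                 "GGGGTTTTAAAACCCCTA"),
                    PF2U = c(3L, 1L, 0L), PF2S = c(0L, 2L, 2L),
                    stringsAsFactors = FALSE)
  classes <- c("miRNA", "rRNA", "unannotated")
  names(classes) <- col$sequence
  s <- summarize_annotation(col, classes)
  cc <- s$counts
  cls_cols <- c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "unannotated")
  expect_equal(rowSums(cc[, cls_cols]), cc$total)
  u2 <- cc[cc$library == "PF2U" & cc$measure == "unique", ]
  expect_equal(u2$total, 2)
  t2s <- cc[cc$library == "PF2S" & cc$measure == "total", ]
  expect_equal(t2s$rRNA, 2)
  expect_equal(s$percent$rRNA[s$percent$library == "PF2S" &
                                s$percent$measure == "total"], 50.00)

  # all unannotated -> 100.00 / 0.00
  cls_all <- stats::setNames(rep("unannotated", 3), col$sequence)
  s2 <- summarize_annotation(col, cls_all)
  expect_true(all(s2$percent$unannotated == 100))
  expect_true(all(s2$percent$miRNA == 0))
})

test_that("percentage rounding is half away from zero at two decimals", {
  expect_equal(annotation_percentage(125, 1000), 12.50)
  expect_equal(round_half_up(0.125, 2), 0.13)   # base round() would give 0.12
  expect_equal(round_half_up(17.0245, 2), 17.02)
})
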