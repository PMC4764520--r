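mirna <- "GATTACAGATTACAGATTACA"   # 21 nt

# a transcript with a perfectly complementary site at 0-based position 60
site_transcript <- function(site = revcomp(mirna), pos0 = 60, len = 300) {
  set.seed(99)
  s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  paste0(substr(s, 1, pos0), site, substr(s, pos0 + nchar(site) + 1, len))
}

test_that("map_signatures reports all exact forward hits, 0-based", {
  tr <- data.frame(id = "t1", sequence = site_transcript())
  sig <- substr(tr$sequence, 41, 71)   # transcript[40:71) 0-based
  hits <- map_signatures(sig, tr)
  expect_equal(hits$position0, 40L)

  mm <- paste0("A", substr(sig, 2, 31))
  mm <- if (mm == sig) paste0("C", substr(sig, 2, 31)) else mm
  expect_equal(nrow(map_signatures(mm, tr)), 0L)

  two <- data.frame(id = c("t1", "t2"),
                    sequence = rep(tr$sequence, 2))
  expect_equal(nrow(map_signatures(sig, two)), 2L)
})

test_that("extend_site adds upstream sequence and flags truncation", {
  tr <- site_transcript()
  w <- extend_site(tr, 100, 31)
  expect_equal(w$start0, 85L)
  expect_equal(w$end0, 131L)
  expect_false(w$truncated)
  expect_equal(w$sequence, substr(tr, 86, 131))

  wb <- extend_site(tr, 5, 31)
  expect_equal(wb$start0, 0L)
  expect_true(wb$truncated)
})

test_that("score_site scores complementarity with wobbles and 10/11 doubling", {
  tr <- site_transcript()
  al <- score_site("miR-X", mirna, "t1", tr, 60, 10)
  expect_equal(al$score, 0)
  expect_equal(al$cleavage_pos0, 60 + 21 - 10)
  expect_equal(al$match_line, strrep("|", 21))

  # single G:U wobble at miRNA position 3 (mirna[3] = T, site base G)
  site <- strsplit(revcomp(mirna), "")[[1]]
  site[21 - 3 + 1] <- "G"
  tr_gu <- site_transcript(paste(site, collapse = ""))
  al_gu <- score_site("miR-X", mirna, "t1", tr_gu, 60, 10)
  expect_equal(al_gu$score, 0.5)
  expect_true(grepl("o", al_gu$match_line))

  # single mismatch opposite miRNA position 10 scores 2 but is still <= 4
  site2 <- strsplit(revcomp(mirna), "")[[1]]
  p <- 21 - 10 + 1
  site2[p] <- setdiff(c("A", "C", "G", "T"),
                      c(site2[p], chartr("ACGT", "TGCA", substr(mirna, 10, 10)),
                        "G", "T"))[1]
  tr_mm <- site_transcript(paste(site2, collapse = ""))
  al_mm <- score_site("miR-X", mirna, "t1", tr_mm, 60, 10)
  expect_equal(al_mm$score, 2)

  # five plain mismatches exceed the threshold
  site5 <- strsplit(revcomp(mirna), "")[[1]]
  for (q in c(2, 4, 6, 8, 14)) {
    j <- 21 - q + 1
    site5[j] <- setdiff(c("A", "C", "G", "T"),
                        c(site5[j],
                          chartr("ACGT", "TGCA", substr(mirna, q, q)),
                          "G", "T"))[1]
  }
  tr5 <- site_transcript(paste(site5, collapse = ""))
  expect_null(score_site("miR-X", mirna, "t1", tr5, 60, 10))
})

test_that("validate_cleavage accepts only positions 10 and 11", {
  tr <- site_transcript()
  al <- score_site("miR-X", mirna, "t1", tr, 60, 10)
  expect_true(validate_cleavage(al, 60 + 21 - 10))   # opposite position 10
  expect_true(validate_cleavage(al, 60 + 21 - 11))   # opposite position 11
  expect_false(validate_cleavage(al, 60 + 21 - 9))
})

test_that("build_tplot accumulates abundances and conserves mass", {
  tr <- data.frame(id = "t1", sequence = site_transcript())
  # two distinct signatures (different lengths) share the 5' end at 40
  sigs <- data.frame(sequence = c(substr(tr$sequence, 41, 71),
                                  substr(tr$sequence, 41, 65),
                                  substr(tr$sequence, 101, 131)),
                     DG = c(3L, 5L, 2L))
  mapped <- map_signatures(sigs, tr)
  tp <- build_tplot("t1", nchar(tr$sequence), mapped)
  expect_equal(tp$counts[41], 8)
  expect_equal(tp$counts[101], 2)
  expect_equal(sum(tp$counts), sum(mapped$count))

  tp0 <- build_tplot("t1", 100, mapped[0, ])
  expect_true(all(tp0$counts == 0))
})

test_that("categorize_site implements the I/II/III rules", {
  expect_equal(categorize_site(c(0, 0, 50, 0, 3), 2), "I")
  expect_equal(categorize_site(c(10, 10, 10), 1), "III")
  expect_equal(categorize_site(c(2, 9, 9, 1), 1), "II")
})

test_that("call_targets recovers a planted target and rejects scrambles", {
  tr <- data.frame(id = "t1", sequence = site_transcript())
  cleav0 <- 60 + 21 - 10
  sig <- substr(tr$sequence, cleav0 + 1, cleav0 + 31)
  sigs <- data.frame(sequence = sig, DG = 20L)
  calls <- call_targets(data.frame(id = "miR-X", sequence = mirna), tr, sigs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$cleavage_pos0, cleav0)
  expect_equal(calls$category, "I")
  expect_true(all(calls$score <= 4))
  expect_true(all(calls$cleavage_mirna_pos %in% c(10L, 11L)))

  scram <- data.frame(id = "decoy", sequence = shuffle_dinucleotide(mirna))
  expect_equal(nrow(call_targets(scram, tr, sigs)), 0L)

  # two miRNAs targeting one transcript give two calls
  mir2 <- "TTGGCCAATTGGCCAATTGCA"
  site2 <- revcomp(mir2)
  tr2seq <- paste0(site_transcript(), site2,
                   strrep("A", 5), strrep("C", 40))
  tr2 <- data.frame(id = "t1", sequence = tr2seq)
  c2 <- 300 + 21 - 10
  sigs2 <- data.frame(sequence = c(substr(tr2seq, cleav0 + 1, cleav0 + 31),
                                   substr(tr2seq, c2 + 1, c2 + 31)),
                      DG = c(20L, 15L))
  calls2 <- call_targets(data.frame(id = c("miR-X", "miR-Y"),
                                    sequence = c(mirna, mir2)), tr2, sigs2)
  expect_equal(sort(unique(calls2$mirna)), c("miR-X", "miR-Y"))
})

test_that("degradome closed loop: planted recovery and decoy silence", {
  b <- benchmark_degradome_recovery(seed = 21, n_targets = 12, n_decoys = 6)
  expect_equal(b$site_exact_recovery, 1.0)
  expect_equal(b$category_I_rate, 1.0)
  expect_equal(b$decoy_calls_strict, 0L)
})
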