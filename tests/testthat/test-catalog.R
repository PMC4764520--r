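test_that("match_conserved respects the two-mismatch budget", {
  ref <- data.frame(id = "miR1", sequence = "ACGTACGTACGTACGTACGTA",
                    stringsAsFactors = FALSE)
  m0 <- match_conserved("ACGTACGTACGTACGTACGTA", ref)
  expect_equal(m0$n_mismatch, 0L)

  two <- "TTGTACGTACGTACGTACGTA"   # 2 substitutions
  m2 <- match_conserved(two, ref)
  expect_equal(m2$n_mismatch, 2L)

  three <- "TTGTACGTACGTACGTACGTT"  # 3 substitutions
  expect_equal(nrow(match_conserved(three, ref)), 0L)
})

test_that("match_conserved counts length differences toward the budget", {
  ref <- data.frame(id = "miR1", sequence = "ACGTACGTACGTACGTACGTA")
  shorter <- substr(ref$sequence, 1, 19)           # 2-nt overhang
  expect_equal(match_conserved(shorter, ref)$n_mismatch, 2L)
  shorter_sub <- sub("^A", "G", substr(ref$sequence, 1, 20))  # 1 + 1
  expect_equal(match_conserved(shorter_sub, ref)$n_mismatch, 2L)
  too_far <- sub("^A", "G", substr(ref$sequence, 1, 19))      # 2 + 1
  expect_equal(nrow(match_conserved(too_far, ref)), 0L)
})

test_that("match_conserved distance is symmetric and reports all ties", {
  a <- "ACGTACGTACGTACGTACGTA"
  b <- "ACGAACGTACGTACGTACG"   # vs a: 1 sub + 2-nt length difference? no: 1 sub, len 19
  d1 <- match_conserved(a, data.frame(id = "x", sequence = b),
                        max_mismatch = 10)$n_mismatch
  d2 <- match_conserved(b, data.frame(id = "x", sequence = a),
                        max_mismatch = 10)$n_mismatch
  expect_equal(d1, d2)

  ref <- data.frame(id = c("m1", "m2"),
                    sequence = c("ACGTACGTACGTACGTACGTA",
                                 "ACGTACGTACGTACGTACGTT"))
  hits <- match_conserved("ACGTACGTACGTACGTACGTC", ref)
  expect_setequal(hits$ref_id, c("m1", "m2"))   # tied at distance 1
  expect_true(all(hits$n_mismatch == 1L))
})

test_that("match_conserved seed filter agrees with brute force", {
  set.seed(31)
  ref <- data.frame(id = sprintf("m%02d", 1:20),
                    sequence = vapply(1:20, function(i)
                      paste(sample(c("A", "C", "G", "T"), 21, TRUE),
                            collapse = ""), character(1)))
  reads <- c(ref$sequence[1:5],
             vapply(ref$sequence[6:10], function(s) {
               ch <- strsplit(s, "")[[1]]
               p <- sample(21, 2)
               ch[p] <- c("A", "C", "G", "T")[(match(ch[p], c("A", "C", "G",
                                                              "T")) %% 4) + 1]
               paste(ch, collapse = "")
             }, character(1), USE.NAMES = FALSE),
             vapply(1:30, function(i)
               paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""),
               character(1)))
  fast <- match_conserved(reads, ref, max_mismatch = 2)
  # brute force over all pairs
  brute <- do.call(rbind, lapply(unique(reads), function(r) {
    d <- vapply(ref$sequence, function(s) {
      l <- min(nchar(r), nchar(s))
      sum(strsplit(substr(r, 1, l), "")[[1]] !=
            strsplit(substr(s, 1, l), "")[[1]]) + abs(nchar(r) - nchar(s))
    }, numeric(1))
    k <- which(d <= 2 & d == min(d))
    if (!length(k)) return(NULL)
    data.frame(sequence = r, ref_id = ref$id[k], n_mismatch = d[k],
               row.names = NULL)
  }))
  fast_key <- sort(paste(fast$sequence, fast$ref_id, fast$n_mismatch))
  brute_key <- sort(paste(brute$sequence, brute$ref_id, brute$n_mismatch))
  expect_equal(fast_key, brute_key)
})

test_that("excise_precursors clips at bounds and never exceeds the cap", {
  refseq <- paste(rep("ACGT", 500), collapse = "")   # 2 kb
  w <- excise_precursors(refseq, 500, 521, "+")
  expect_true(all(w$end0 - w$start0 <= 350))
  expect_true(all(substring(refseq, w$start0 + 1, w$end0) == w$sequence))
  # mature coordinates point at the mature inside each window
  for (i in 1:2) {
    expect_equal(substr(w$sequence[i], w$mature_start0[i] + 1,
                        w$mature_end0[i]),
                 substr(refseq, 501, 521))
  }
  wb <- excise_precursors(refseq, 3, 24, "+")
  expect_true(any(wb$start0 == 0))
  expect_error(excise_precursors(refseq, 1990, 2011, "+"),
               "outside reference")
})

test_that("fold_rna recovers designed structures", {
  f <- fold_rna("GGGGAAAACCCC")
  expect_equal(f$structure, "((((....))))")
  expect_equal(f$score, 15)   # 4 GC pairs + 3 stacks

  f0 <- fold_rna("AAAAAAAAAAAA")
  expect_equal(f0$structure, strrep(".", 12))
  expect_equal(f0$mfe_estimate, 0)

  # designed 48-nt hairpin: 21-bp stem, 6-nt loop
  stem <- "GATTACAGATTACAGATTACA"
  hp <- paste0(stem, "AACAAC", revcomp(stem))
  fh <- fold_rna(hp)
  expect_equal(sum(strsplit(fh$structure, "")[[1]] == "("), 21)
  pt <- pair_table(fh$structure)
  expect_true(all(pt[1:21] == 48:28))   # single stem, nested

  expect_error(fold_rna("ACGTN"), "non-RNA")
})

test_that("fold_rna structures are valid and agree with enumeration", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(8:25, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    f <- fold_rna(s)
    expect_equal(f$score, fold_exhaustive(s)$score, info = s)
    pt <- pair_table(f$structure)   # errors on unbalanced brackets
    paired <- which(pt > 0)
    for (p in paired[pt[paired] > paired]) {
      pair <- paste0(substr(s, p, p), substr(s, pt[p], pt[p]))
      expect_true(pair %in% c("AT", "TA", "GC", "CG", "GT", "TG"))
      expect_true(pt[p] - p - 1 >= 3 ||
                    any(pt[(p + 1):(pt[p] - 1)] > 0))  # loops >= 3
    }
    expect_true(f$mfe_estimate <= 0)
  }
})

test_that("find_star applies the 2-nt 3' overhang rule", {
  mature <- "GATTACAGATTACAGATTACA"
  ext <- "GGCCGGCA"
  prec <- paste0(ext, mature, "ACACACACACA", revcomp(mature), revcomp(ext))
  f <- fold_rna(prec)
  st <- find_star(prec, f$structure, 8, 29)
  # star pairs mature[3..21] plus a 2-nt 3' overhang into the extension
  expected <- substr(prec, 8 + 21 + 11 + 1 + 2, 8 + 21 + 11 + 21 + 2)
  expect_equal(st$star, expected)

  reads <- data.frame(sequence = expected, L1 = 3L)
  expect_true(find_star(prec, f$structure, 8, 29, reads)$observed)
  reads0 <- data.frame(sequence = "AAAAAAAAAAAAAAAAAAAAA", L1 = 1L)
  expect_false(find_star(prec, f$structure, 8, 29, reads0)$observed)
})

test_that("find_star errors when the mature spans the loop", {
  mature <- "GATTACAGATTACAGATTACA"
  prec <- paste0("GGCCGGCA", mature, "ACACACACACA", revcomp(mature),
                 "TGCCGGCC")
  f <- fold_rna(prec)
  # "mature" centred on the loop region
  expect_error(find_star(prec, f$structure, 20, 41), "mature_in_loop")
})

test_that("check_meyers passes designed hairpins and flags violations", {
  mature <- "GATTACAGATTACAGATTACA"
  ext <- "GGCCGGCA"
  prec <- paste0(ext, mature, "ACACACACACA", revcomp(mature), revcomp(ext))
  v <- check_meyers(prec, 8, 29)
  expect_true(v$pass)
  expect_equal(v$duplex_mismatches, 0L)
  expect_equal(v$asymmetric_bulge_nt, 0L)

  # boundary: exactly 5 unpaired mature positions fails the <= 4 rule
  # (structure supplied directly so only the duplex criterion is at stake)
  skip_pos <- c(13, 15, 17, 19, 21)
  open_pos <- setdiff(1:29, skip_pos)
  ch <- rep(".", 69)
  ch[open_pos] <- "("
  ch[70 - open_pos] <- ")"
  v2 <- check_meyers(prec, 8, 29, structure = paste(ch, collapse = ""),
                     mfe_estimate = -30)
  expect_false(v2$pass)
  expect_equal(v2$duplex_mismatches, 5L)
  expect_equal(v2$reasons, "duplex_mismatches")

  # same construction with 4 unpaired positions still passes
  skip4 <- c(13, 15, 17, 19)
  open4 <- setdiff(1:29, skip4)
  ch4 <- rep(".", 69)
  ch4[open4] <- "("
  ch4[70 - open4] <- ")"
  v2b <- check_meyers(prec, 8, 29, structure = paste(ch4, collapse = ""),
                      mfe_estimate = -30)
  expect_true(v2b$pass)

  # short precursor fails the length criterion
  short <- paste0(mature, "ACACA", revcomp(substr(mature, 3, 21)))
  v3 <- check_meyers(short, 0, 21)
  expect_false(v3$pass)
  expect_true("precursor_length" %in% v3$reasons)
})

test_that("planted hairpins pass and shuffled controls fail", {
  b <- benchmark_hairpin_criteria(seed = 101, n = 12)
  expect_equal(b$planted_pass_rate, 1.0)
  expect_equal(b$shuffled_fail_rate, 1.0)
})

test_that("dinucleotide shuffle preserves dinucleotide composition", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  dinu <- function(x) {
    ch <- strsplit(x, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  sh <- shuffle_dinucleotide(s)
  expect_equal(nchar(sh), nchar(s))
  expect_equal(dinu(sh), dinu(s))
})
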