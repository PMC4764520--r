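test_that("normalize_rpm applies the exact formula without pseudo-counts", {
  expect_equal(normalize_rpm(0, 1e6), 0)
  expect_equal(normalize_rpm(12345, 12345), 1e6)
  expect_equal(normalize_rpm(341123, 16961959), 341123 / 16961959 * 1e6)
})

test_that("fold_change is log2 of numerator over baseline", {
  expect_equal(fold_change(5, 5), 0)
  expect_equal(fold_change(1, 2), 1)
  expect_equal(fold_change(2, 1), -1)
  expect_error(fold_change(0, 1))
})

test_that("ac_pvalue closed forms at equal totals", {
  r <- ac_pvalue(0, 0, 1e6, 1e6)
  expect_equal(r$C, 0.5, tolerance = 1e-12)      # p(0|0) = 1/2
  expect_equal(r$D, 1.0, tolerance = 1e-12)

  r2 <- ac_pvalue(5, 0, 1e6, 1e6)
  expect_equal(r2$C, 1 / 64, tolerance = 1e-12)  # p(0|5) = 2^-6

  # normalization: the lower tail reaches 1
  for (x in c(0, 3, 17)) {
    expect_equal(ac_pvalue(x, 10 * x + 200, 5e5, 5e5)$C, 1,
                 tolerance = 1e-9)
  }
})

test_that("ac_pvalue tails match the negative-binomial identity", {
  # p(y|x) is NB(size = x + 1, prob = n1 / (n1 + n2)); pnbinom is an
  # independent route to the same tails
  grid <- expand.grid(x = c(0, 1, 7, 30, 120), y = c(0, 2, 9, 40, 200),
                      r = c(0.5, 1, 2.7))
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; y <- grid$y[i]; r <- grid$r[i]
    res <- ac_pvalue(x, y, 1e6, r * 1e6)
    expect_equal(res$C, stats::pnbinom(y, size = x + 1, prob = 1 / (1 + r)),
                 tolerance = 1e-10)
    expect_equal(res$D,
                 stats::pnbinom(y - 1, size = x + 1, prob = 1 / (1 + r),
                                lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("C(y) and the complementary upper tail partition to 1", {
  for (i in 1:20) {
    x <- sample(0:50, 1); y <- sample(0:50, 1)
    res <- ac_pvalue(x, y, 3e5, 7e5)
    res_next <- ac_pvalue(x, y + 1, 3e5, 7e5)
    expect_equal(res$C + res_next$D, 1, tolerance = 1e-9)
  }
})

test_that("relabeling the pair negates log2fc and mirrors the P-value", {
  x <- 12; y <- 30; n1 <- 2e5; n2 <- 3e5
  expect_equal(fold_change(normalize_rpm(x, n1), normalize_rpm(y, n2)),
               -fold_change(normalize_rpm(y, n2), normalize_rpm(x, n1)))
  # two-sided p is symmetric up to discreteness; exact at scale
  a <- ac_pvalue(1200, 1450, 2e5, 2e5)
  b <- ac_pvalue(1450, 1200, 2e5, 2e5)
  expect_equal(a$p, b$p, tolerance = 2e-3)
  # within one call C and D overlap only in the observed point:
  # C(y) + D(y) = 1 + p(y|x), with the point mass from an independent route
  for (case in list(c(0, 0), c(5, 2), c(40, 80))) {
    r1 <- ac_pvalue(case[1], case[2], 2e5, 3e5)
    pmass <- stats::dnbinom(case[2], size = case[1] + 1,
                            prob = 1 / (1 + 3e5 / 2e5))
    expect_equal(r1$C + r1$D, 1 + pmass, tolerance = 1e-9)
  }
})

test_that("classify_de applies the low-expression rule and thresholds", {
  f <- classify_de(0.4, 0.7, 0.001)
  expect_equal(f$status, "filtered")

  up <- classify_de(1, 4, 0.001)
  expect_equal(up$status, "up")
  expect_equal(up$log2fc, 2)

  ns <- classify_de(4, 7, 0.3)
  expect_equal(ns$status, "ns")

  # one side below 1 RPM is floored, not filtered (default behaviour)
  fl <- classify_de(0.2, 8, 0.001)
  expect_equal(fl$status, "up")
  expect_equal(fl$log2fc, 3)
  # ... unless the strict variant is requested
  expect_equal(classify_de(0.2, 8, 0.001, floor_single = FALSE)$status,
               "filtered")
})

test_that("compare_libraries flags a spiked miRNA and leaves nulls alone", {
  counts <- matrix(c(4000L, 1000L,
                     500L, 510L,
                     80L, 76L),
                   ncol = 2, byrow = TRUE,
                   dimnames = list(c("spiked", "null1", "null2"),
                                   c("A", "B")))
  totals <- c(A = 2e5, B = 2e5)
  de <- compare_libraries(counts, totals, "A/B")
  # baseline is B; spiked has 4x in A
  expect_equal(de$status[de$id == "spiked"], "up")
  expect_true(all(de$status[de$id != "spiked"] == "ns"))
  expect_equal(attr(de, "n_up"), 1L)

  de_same <- compare_libraries(counts[, c(1, 1),
                                      drop = FALSE] |>
                                 `colnames<-`(c("A", "B")),
                               totals, "A/B")
  expect_true(all(de_same$log2fc == 0))
  expect_true(all(de_same$status == "ns"))

  de_empty <- compare_libraries(counts[0, , drop = FALSE], totals, "A/B")
  expect_equal(nrow(de_empty), 0L)

  expect_error(compare_libraries(counts, totals, "A/C"),
               "unknown libraries")
})

test_that("salt_associated implements the comparison-set logic", {
  mk <- function(status) {
    data.frame(id = c("m1", "m2", "m3"),
               status = status, stringsAsFactors = FALSE)
  }
  # m1: up everywhere salt-wise, down in 4U/2U -> in all three sets
  # m2: up in 2S/2U only -> in none
  # m3: significant everywhere, same trend in 4S/2S and 4U/2U -> dropped
  de_2S2U <- mk(c("up", "up", "up"))
  de_4S4U <- mk(c("up", "ns", "down"))
  de_4S2S <- mk(c("up", "ns", "up"))
  de_4U2U <- mk(c("down", "ns", "up"))
  s <- salt_associated(de_2S2U, de_4S4U, de_4S2S, de_4U2U)
  expect_setequal(s$salt_responsive, c("m1", "m3"))
  expect_setequal(s$cross_ploidy, c("m1", "m3"))
  expect_equal(s$tolerance_candidates, "m1")
})

test_that("ddct averages triplicates and applies the double delta", {
  equal_ct <- data.frame(
    gene = rep(c("target", "reference"), each = 6),
    condition = rep(rep(c("treated", "control"), each = 3), 2),
    ct = rep(20, 12))
  expect_equal(ddct(equal_ct)$relative_expression, 1.0)

  expect_equal(ddct(c(21, 20, 20, 20))$relative_expression, 0.5)
  r <- ddct(c(24, 20, 22, 20))
  expect_equal(r$ddct, 2)
  expect_equal(r$relative_expression, 0.25)

  tri <- data.frame(
    gene = rep(c("target", "reference"), each = 6),
    condition = rep(rep(c("treated", "control"), each = 3), 2),
    ct = c(24.1, 24.0, 23.9, 22.0, 22.1, 21.9,   # target: treated, control
           20.0, 20.1, 19.9, 20.1, 19.9, 20.0))  # reference
  expect_equal(ddct(tri)$relative_expression, 0.25, tolerance = 1e-6)
})

test_that("expression_matrix aggregates collapsed counts per assignment", {
  col <- data.frame(sequence = c("AAAA", "CCCC", "GGGG"),
                    L1 = c(5L, 3L, 2L), L2 = c(0L, 1L, 7L))
  asn <- data.frame(sequence = c("AAAA", "CCCC", "GGGG"),
                    ref_id = c("m1", "m1", "m2"))
  m <- expression_matrix(col, asn)
  expect_equal(m["m1", "L1"], 8L)
  expect_equal(m["m2", "L2"], 7L)
})

test_that("type-I error of the exact test is in the documented band", {
  rates <- vapply(1:3, benchmark_null_type1, numeric(1))
  expect_true(all(rates >= 0.01 & rates <= 0.08))
})
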