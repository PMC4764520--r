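# exact-rational oracle for the count-ratio exact test, computed with
# python's fractions (arbitrary precision); returns a data.frame of
# C (lower tail) and D (upper tail) for all x, y <= xmax at the
# given count-total ratios
ac_oracle_table <- function(xmax = 30) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "xmax = int(sys.argv[1])",
    "for num, den in [(1, 2), (1, 1), (2, 1)]:",
    "    r = Fraction(num, den)",
    "    for x in range(xmax + 1):",
    "        C = Fraction(0)",
    "        for y in range(xmax + 1):",
    "            p = r**y * comb(x + y, y) / (1 + r)**(x + y + 1)",
    "            C += p",
    "            D = 1 - (C - p)",
    "            print('%d\\t%d\\t%d\\t%d\\t%r\\t%r' %",
    "                  (x, y, num, den, float(C), float(D)))"
  ), script)
  out <- system2("python", c(script, xmax), stdout = TRUE)
  df <- utils::read.delim(text = paste(out, collapse = "\n"), header = FALSE)
  names(df) <- c("x", "y", "num", "den", "C", "D")
  df
}

# small deterministic record builder
make_records <- function(seqs, quals = NULL) {
  data.frame(id = sprintf("r%d", seq_along(seqs)), sequence = seqs,
             quality = if (is.null(quals)) rep(NA_character_, length(seqs)) else quals,
             stringsAsFactors = FALSE)
}

small_sim_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed, n_conserved = 12L, n_novel = 4L, n_transcripts = 5L,
    n_spiked = 4L,
    library_totals = c(PF2U = 5000, PF2S = 5000, PF4U = 5000, PF4S = 5000),
    degradome = list(n_targets = 4L, on_site_fraction = 0.8,
                     sig_length = 31L, background_positions = 12L,
                     background_rate = 1L, mismatch_range = 0:2))
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
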