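#!/usr/bin/env Rscript
# Degradome target calling against the planted truth; t-plots per target.
source("analysis/00_config.R")

ref <- simulate_reference(ana_config)
sigs <- read_collapsed_fasta("scratch/analysis_data/degradome.fasta", "DG")
calls <- call_targets(ref$mirna_truth[, c("id", "sequence")],
                      ref$transcripts, sigs)
write.table(calls, "results/targets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
dir.create("results/tplot", showWarnings = FALSE)
tplots <- attr(calls, "tplots")
for (t in unique(calls$transcript)) {
  prof <- tplots[[t]]$counts
  nz <- which(prof > 0)
  write.table(data.frame(position0 = nz - 1L, count = prof[nz]),
              file.path("results/tplot", paste0(t, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

tt <- ref$target_truth
key <- paste(calls$mirna, calls$transcript, calls$cleavage_pos0)
tkey <- paste(tt$mirna, tt$transcript, tt$cleavage_pos0)
message(sprintf("%d calls (%s); planted recovered site-exactly: %d / %d",
                nrow(calls),
                paste(names(table(calls$category)), table(calls$category),
                      sep = ":", collapse = " "),
                sum(tkey %in% key), nrow(tt)))
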