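#!/usr/bin/env Rscript
# Clean and collapse the four libraries, compute length distributions and
# the annotation summary.
source("analysis/00_config.R")

ref <- simulate_reference(ana_config)
params <- cleaning_params(adapter3 = ana_config$adapter)

collapsed_list <- list(); totals <- numeric(0); ld <- list(); st <- list()
for (lib in names(ana_config$library_totals)) {
  reads <- read_fastq(file.path("scratch/analysis_data", paste0(lib, ".fastq")))
  cl <- clean_reads(reads, params)
  st[[lib]] <- data.frame(library = lib, t(cl$stats))
  collapsed_list[[lib]] <- collapse_reads(cl$records, lib)
  totals[lib] <- cl$stats[["retained"]]
  ld[[lib]] <- cbind(library = lib,
                     length_distribution(collapsed_list[[lib]], lib))
}
collapsed <- merge_collapsed(collapsed_list)
saveRDS <- NULL  # intermediate state is re-derived, never serialised

hits <- match_conserved(collapsed, ref$mature_ref)
classes <- classify_reads(collapsed, ref$ncrna, mirna_hits = hits$sequence)
summ <- summarize_annotation(collapsed, classes)

write.table(do.call(rbind, st), "results/cleaning_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, ld), "results/length_dist.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ$counts, "results/annotation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ$percent, "results/annotation_percent.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tot <- summ$counts[summ$counts$measure == "total", ]
message(sprintf("clean totals: %s", paste(names(totals), totals,
                                          sep = "=", collapse = " ")))
message(sprintf("miRNA share of total reads: %.1f%%-%.1f%%",
                min(100 * tot$miRNA / tot$total),
                max(100 * tot$miRNA / tot$total)))
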