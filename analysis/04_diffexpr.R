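#!/usr/bin/env Rscript
# Exact-test differential expression over the four comparisons and the
# salt-associated set logic, scored against the spike-in truth.
source("analysis/00_config.R")

ref <- simulate_reference(ana_config)
sim <- simulate_srna_libraries(ana_config, ref)   # for the spike truth
params <- cleaning_params(adapter3 = ana_config$adapter)
collapsed_list <- list(); totals <- numeric(0)
for (lib in names(ana_config$library_totals)) {
  reads <- read_fastq(file.path("scratch/analysis_data", paste0(lib, ".fastq")))
  cl <- clean_reads(reads, params)
  collapsed_list[[lib]] <- collapse_reads(cl$records, lib)
  totals[lib] <- cl$stats[["retained"]]
}
collapsed <- merge_collapsed(collapsed_list)
hits <- match_conserved(collapsed, ref$mature_ref)
mat <- expression_matrix(collapsed, hits)

pairs <- c("PF2S/PF2U", "PF4U/PF2U", "PF4S/PF4U", "PF4S/PF2S")
de <- list()
for (p in pairs) {
  de[[p]] <- compare_libraries(mat, totals, p)
  write.table(de[[p]], file.path("results",
                                 paste0("de_", gsub("/", "_vs_", p), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d up, %d down of %d tested", p,
                  attr(de[[p]], "n_up"), attr(de[[p]], "n_down"), nrow(mat)))
}
salt <- salt_associated(de[["PF2S/PF2U"]], de[["PF4S/PF4U"]],
                        de[["PF4S/PF2S"]], de[["PF4U/PF2U"]])
write.table(data.frame(id = salt$salt_responsive,
                       cross_ploidy = salt$salt_responsive %in%
                         salt$cross_ploidy,
                       tolerance_candidate = salt$salt_responsive %in%
                         salt$tolerance_candidates),
            "results/salt_associated.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sp <- sim$spikes[sim$spikes$pair == "PF2S/PF2U", ]
sp$ref_id <- ref$mirna_truth$ref_id[match(sp$mirna, ref$mirna_truth$id)]
d <- de[["PF2S/PF2U"]]
ok <- sum((sp$log2fc > 0 & d$status[match(sp$ref_id, d$id)] == "up") |
            (sp$log2fc < 0 & d$status[match(sp$ref_id, d$id)] == "down"),
          na.rm = TRUE)
message(sprintf("salt-responsive set: %d; tolerance candidates: %d",
                length(salt$salt_responsive),
                length(salt$tolerance_candidates)))
message(sprintf("spike recovery in PF2S/PF2U: %d / %d", ok, nrow(sp)))
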