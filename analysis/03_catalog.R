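#!/usr/bin/env Rscript
# Conserved matching and novel hairpin discovery on the collapsed reads.
source("analysis/00_config.R")

ref <- simulate_reference(ana_config)
params <- cleaning_params(adapter3 = ana_config$adapter)
collapsed_list <- list()
for (lib in names(ana_config$library_totals)) {
  reads <- read_fastq(file.path("scratch/analysis_data", paste0(lib, ".fastq")))
  collapsed_list[[lib]] <- collapse_reads(clean_reads(reads, params)$records,
                                          lib)
}
collapsed <- merge_collapsed(collapsed_list)

hits <- match_conserved(collapsed, ref$mature_ref)
mat <- expression_matrix(collapsed, hits)
write.table(data.frame(id = rownames(mat), mat), "results/conserved.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

classes <- classify_reads(collapsed, ref$ncrna, mirna_hits = hits$sequence)
unann <- names(classes)[classes == "unannotated"]
tot_cnt <- rowSums(collapsed[, setdiff(names(collapsed), "sequence")])
cand <- collapsed$sequence[collapsed$sequence %in% unann]
cand <- head(cand[order(-tot_cnt[match(cand, collapsed$sequence)])], 300)
novel <- discover_novel(collapsed, cand, ref$transcripts,
                        exclude_seqs = hits$sequence)
write.table(novel, "results/novel.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth_novel <- ref$mirna_truth$sequence[ref$mirna_truth$is_novel]
message(sprintf("conserved ids matched: %d / %d", nrow(mat),
                sum(!ref$mirna_truth$is_novel)))
message(sprintf("novel loci: %d called; %d / %d planted recovered; %d with observed star",
                nrow(novel), sum(truth_novel %in% novel$sequence),
                length(truth_novel),
                if (nrow(novel)) sum(novel$star_observed) else 0))
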