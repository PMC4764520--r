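#!/usr/bin/env Rscript
# Generate the reference sets, the four sRNA libraries and the degradome
# library with full ground truth.
source("analysis/00_config.R")

ref <- simulate_reference(ana_config)
sim <- simulate_srna_libraries(ana_config, ref, dir = "scratch/analysis_data")
dgs <- simulate_degradome(ana_config, ref, dir = "scratch/analysis_data")

write_fasta(ref$transcripts, "scratch/analysis_data/transcripts.fasta")
write_fasta(ref$mature_ref, "scratch/analysis_data/mature_reference.fasta", rna = TRUE)
for (cl in names(ref$ncrna)) {
  write_fasta(ref$ncrna[[cl]], file.path("scratch/analysis_data",
                                         paste0("ncrna_", cl, ".fasta")))
}
write.table(ref$mirna_truth, "scratch/analysis_data/truth_mirna.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$expression_truth, "scratch/analysis_data/truth_expression.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dgs$target_truth, "scratch/analysis_data/truth_targets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d miRNA loci (%d novel) on %d transcripts; %d reads/library; %d planted targets",
                nrow(ref$mirna_truth), sum(ref$mirna_truth$is_novel),
                nrow(ref$transcripts),
                ana_config$library_totals[[1]], nrow(dgs$target_truth)))
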