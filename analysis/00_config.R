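# Shared configuration for the analysis scripts: one moderate simulated
# dataset standing in for the four sRNA libraries plus the degradome.
library(salmir)

ana_config <- simulation_config(
  seed = 20160219L,
  n_conserved = 60L, n_novel = 8L, n_transcripts = 20L,
  n_spiked = 12L,
  library_totals = c(PF2U = 3e4, PF2S = 3e4, PF4U = 3e4, PF4S = 3e4),
  degradome = list(n_targets = 12L, on_site_fraction = 0.8,
                   sig_length = 31L, background_positions = 12L,
                   background_rate = 2L, mismatch_range = 0:2))

dir.create("results", showWarnings = FALSE)
dir.create("scratch/analysis_data", showWarnings = FALSE)
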