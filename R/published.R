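#' Reference annotation counts for the four P. fortunei libraries
#'
#' Per-library unique and total sRNA counts by annotation class from the
#' diploid/tetraploid *Paulownia fortunei* salt-stress sequencing study
#' (libraries PF2U, PF2S, PF4U, PF4S), shipped as a worked example for the
#' annotation-summary arithmetic: the class counts of each row sum exactly
#' to its printed library total, and [annotation_percentage()] reproduces
#' the printed percentages.
#'
#' @return data.frame `library`, `measure` (unique/total), `total`, and the
#'   six class columns.
#' @export
published_annotation_counts <- function() {
  read_tsv(system.file("extdata", "pf_annotation_counts.tsv",
                       package = "salmir", mustWork = TRUE))
}

#' Reference per-library read counts for selected miRNAs
#'
#' Printed per-library read counts for abundant conserved (miR156a/b/c,
#' miR157) and novel (mir6a-h, mir3a/b) miRNA groups from the same study,
#' used as worked examples for normalisation and fold-change arithmetic.
#'
#' @return data.frame `id`, `PF2U`, `PF2S`, `PF4U`, `PF4S`.
#' @export
published_mirna_counts <- function() {
  read_tsv(system.file("extdata", "pf_mirna_counts.tsv",
                       package = "salmir", mustWork = TRUE))
}
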