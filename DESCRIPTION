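Package: salmir
Title: Salt-Responsive miRNA Discovery from Small RNA and Degradome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for identifying salt-stress-responsive
    microRNAs in diploid and tetraploid plants from small RNA sequencing
    libraries. Covers read cleaning and collapsing, annotation of sRNA
    classes, conserved miRNA identification by mismatch-bounded matching,
    novel miRNA discovery by hairpin excision and stem-loop criteria,
    exact-test differential expression of read counts with reads-per-million
    normalisation, comparison-set logic for salt-associated miRNAs,
    degradome (PARE) based target calling with t-plots and category
    assignment, and 2^-ddCt qPCR arithmetic. Includes a synthetic-data
    generator with known truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
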