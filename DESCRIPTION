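Package: taudge
Title: Tissue Specificity and Molecular Evolution from Digital Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digital gene expression analysis of multi-tissue cDNA
    sequencing data of the 454/EST era. Parses tabular BLAST alignments and
    applies best-hit, contaminant-removal, gene-coverage and splice-gap rules;
    aggregates contig read counts to gene level and normalises to
    count-proportion transcripts per million (TPM); computes the tau index of
    tissue specificity with a TPM floor for undetected tissues and a minimum
    read filter; implements a level-stratified resampling null for the sampling
    bias in tau at low read counts, with a one-sample t comparison against the
    observed expression-specificity correlation; performs GO-term
    overrepresentation (one-sided hypergeometric with multiple-testing
    adjustment) and the correlation and group-difference analyses linking
    expression breadth to dN/dS. A seeded synthetic-data generator emulates the
    count structure of such studies and carries ground truth for
    parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
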