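# Shared fixtures built in code.

six_tissues <- c("embryo", "liver", "muscle", "skin", "spleen", "testes")

small_config <- function(n_genes = 300, depth = 50000, seed = 1, ...) {
  simulation_config(
    n_genes = n_genes,
    library_sizes = stats::setNames(rep(depth, 6), six_tissues),
    seed = seed,
    ...
  )
}

# The published seven-library MHC expression table (TPM, one decimal) with its
# library-size footer; used to pin the tau conventions.
mhc_table <- function() {
  read_table3_tsv(system.file("extdata", "mhc_expression_tpm.tsv",
                              package = "taudge"))
}

# Write outfmt-6 lines to a temp file.
write_hits <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

hit_line <- function(q, s, evalue, len = 100, sstart = 1, send = NULL,
                     qstart = 1) {
  send <- send %||% (sstart + len - 1)
  paste(q, s, "98.5", len, 1, 0, qstart, qstart + len - 1, sstart, send,
        format(evalue, scientific = TRUE), round(1.8 * len, 1), sep = "\t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Contig table with known tissue proportions and totals (counts drawn
# multinomially), for bias-simulation tests.
sim_contig_table <- function(n, totals, alpha = 0.5, seed = 1,
                             tissues = six_tissues) {
  withr::with_seed(seed, {
    g <- matrix(stats::rgamma(n * length(tissues), alpha), n)
    p <- g / rowSums(g)
    cnt <- taudge:::rmultinom_rows(totals, p)
    colnames(cnt) <- tissues
    dplyr::bind_cols(
      tibble::tibble(contig_id = sprintf("C%05d", seq_len(n))),
      tibble::as_tibble(cnt)
    )
  })
}

deep_library_sizes <- function(depth = 1e6) {
  stats::setNames(rep(depth, 6), six_tissues)
}
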