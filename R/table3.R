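#' Read a published-style TPM table with a library-size footer
#'
#' Parses a TSV whose first column is the gene name, whose remaining columns
#' are per-tissue TPM (an optional final `tau` column is kept separately), and
#' whose last row, labelled `Library size`, carries the per-library read
#' totals. Thousands separators are accepted. This is the format in which
#' multi-tissue digital-expression tables of the EST/454 era were published.
#'
#' @param path TSV file path.
#' @return List: `tpm` (tibble, gene column first), `library_sizes` (named
#'   numeric), `printed_tau` (named character vector as printed, or `NULL` if
#'   the file has no tau column).
#' @export
read_table3_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  gene_col <- names(raw)[1]
  has_tau <- tolower(names(raw)[ncol(raw)]) == "tau"
  tissue_cols <- setdiff(names(raw), c(gene_col, if (has_tau) names(raw)[ncol(raw)]))
  footer <- raw[[gene_col]] == "Library size"
  if (!any(footer)) abort("no 'Library size' footer row found")
  denum <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))
  library_sizes <- vapply(raw[footer, tissue_cols][1, ], denum, numeric(1))
  body <- raw[!footer, , drop = FALSE]
  tpm <- bind_cols(
    tibble(gene = body[[gene_col]]),
    as_tibble(lapply(body[tissue_cols], denum))
  )
  printed_tau <- if (has_tau) {
    setNames(body[[ncol(raw)]], body[[gene_col]])
  }
  list(tpm = tpm, library_sizes = library_sizes, printed_tau = printed_tau)
}

#' Recompute tau for a published TPM table
#'
#' Applies the package's standard path for TPM-only inputs: integer read
#' counts are back-inferred from TPM and library size, TPM is recomputed from
#' the inferred counts (published TPM is rounded to one decimal; tau is
#' sensitive to that rounding in near-single-tissue profiles), and tau, the
#' read filter and the tissue of maximal expression are computed from the
#' exact values.
#'
#' @param tpm Wide TPM tibble, gene column first.
#' @param library_sizes Named (or ordered) positive library sizes.
#' @inheritParams tau_table
#' @return A [tau_table()] result.
#' @export
#' @examples
#' tab <- tibble::tibble(gene = "CD1A", brain = 0, embryo = 0, liver = 2.5,
#'                       muscle = 0, skin = 0, spleen = 55.6, testes = 0)
#' sizes <- c(brain = 92040, embryo = 323897, liver = 392890, muscle = 325646,
#'            skin = 252349, spleen = 287902, testes = 299755)
#' tau_from_tpm_table(tab, sizes)$tau # 0.817
tau_from_tpm_table <- function(tpm, library_sizes, min_reads = 4,
                               floor_tpm = 2) {
  counts <- infer_counts_from_tpm(tpm, library_sizes)
  tau_table(counts, library_sizes, min_reads = min_reads,
            floor_tpm = floor_tpm)
}

#' Render a publication-style expression table
#'
#' Formats per-gene TPM (one decimal, thousands separator) across libraries
#' with a final tau column (three decimals, `-` when the gene is below the
#' read filter) and a `Library size` footer row.
#'
#' @param tpm Wide TPM tibble, gene column first.
#' @param tau_tbl Matching [tau_table()] result (entity ids = gene names).
#' @param genes Genes to include, in order. Unknown ids are an error; an empty
#'   vector yields header and footer only.
#' @param library_sizes Named (or ordered) positive library sizes.
#' @return Tibble of formatted character columns.
#' @export
make_table3_report <- function(tpm, tau_tbl, genes, library_sizes) {
  gene_col <- names(tpm)[1]
  unknown <- setdiff(genes, tpm[[gene_col]])
  if (length(unknown) > 0) {
    abort(paste0("unknown gene id(s): ", paste(unknown, collapse = ", ")))
  }
  parts <- split_expression_table(tpm, library_sizes)
  library_sizes <- match_library_sizes(library_sizes, parts$value_cols)
  fmt <- function(x) format(round(x, 1), big.mark = ",", nsmall = 1,
                            trim = TRUE, scientific = FALSE)
  rows <- lapply(genes, function(g) {
    i <- match(g, tpm[[gene_col]])
    ti <- match(g, tau_tbl$entity_id)
    tau_chr <- if (!is.na(ti) && !is.na(tau_tbl$tau[ti])) {
      sprintf("%.3f", tau_tbl$tau[ti])
    } else {
      "-"
    }
    as_tibble(c(
      setNames(list(g), "Gene"),
      setNames(as.list(fmt(unlist(tpm[i, parts$value_cols]))),
               parts$value_cols),
      list(tau = tau_chr)
    ))
  })
  footer <- as_tibble(c(
    list(Gene = "Library size"),
    setNames(as.list(format(library_sizes, big.mark = ",", trim = TRUE,
                            scientific = FALSE)),
             parts$value_cols),
    list(tau = "")
  ))
  bind_rows(c(rows, list(footer)))
}
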