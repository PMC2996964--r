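#' Aggregate contig read counts to gene level
#'
#' Sums, per library, the reads of all contigs assigned to each gene. Contigs
#' without an assignment are not discarded: their reads are pooled into a
#' single unannotated bucket row so that total reads are conserved and the
#' unannotated fraction can be reported.
#'
#' @param contig_counts Wide tibble: `contig_id`, optional `length`, one count
#'   column per library.
#' @param assignments Tibble with `contig_id`, `gene_id` (e.g. from
#'   [select_best_hits()] after [flag_contaminants()]). Every `contig_id`
#'   must exist in `contig_counts`.
#' @param unassigned_label Row id used for the unannotated bucket.
#' @return Wide tibble: `gene_id` plus one integer count column per library,
#'   including the unannotated bucket row (present whenever any unassigned
#'   contig has reads).
#' @export
aggregate_contigs_to_genes <- function(contig_counts, assignments,
                                       unassigned_label = "<unannotated>") {
  unknown <- setdiff(assignments$contig_id, contig_counts$contig_id)
  if (length(unknown) > 0) {
    abort(paste0("assignments reference unknown contig(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  parts <- split_expression_table(contig_counts, id_col = "contig_id")
  gene <- assignments$gene_id[match(parts$id, assignments$contig_id)]
  gene[is.na(gene)] <- unassigned_label
  agg <- rowsum(parts$mat, group = gene)
  out <- bind_cols(
    tibble(gene_id = rownames(agg)),
    as_tibble(agg)
  )
  # keep the bucket last for readability
  arrange(out, .data$gene_id == unassigned_label, .data$gene_id)
}

#' Count-proportion TPM normalisation
#'
#' Converts read counts to transcripts per million in the digital-expression
#' (EST/454) sense: `tpm = count / library_size * 1e6`, a read-count
#' proportion with no transcript-length correction. This is deliberately NOT
#' the length-normalised TPM of modern RNA-seq; with per-library read totals
#' as the denominator it reproduces the arithmetic of published
#' tag-count tables.
#'
#' @param counts Wide tibble: id column first, one count column per library.
#' @param library_sizes Positive library sizes, named by count column or in
#'   column order.
#' @return Tibble of the same shape with TPM values in place of counts.
#' @export
#' @examples
#' compute_tpm(
#'   tibble::tibble(gene_id = "TUBB", brain = 2, embryo = 1, liver = 0),
#'   c(brain = 92040, embryo = 323897, liver = 392890)
#' )
compute_tpm <- function(counts, library_sizes) {
  parts <- split_expression_table(counts, library_sizes)
  library_sizes <- match_library_sizes(library_sizes, parts$value_cols)
  if (any(parts$mat < 0)) abort("counts must be non-negative")
  tpm <- sweep(parts$mat, 2, library_sizes, "/") * 1e6
  out <- counts
  out[parts$value_cols] <- as_tibble(tpm)
  out
}

#' Infer integer read counts from TPM values
#'
#' Inverts [compute_tpm()] by nearest-integer (half-up) rounding:
#' `count = round(tpm * library_size / 1e6)`. Needed to apply read-count
#' filters to published TPM tables that do not print the underlying counts.
#'
#' @param tpm Wide tibble: id column first, one TPM column per library.
#' @param library_sizes Positive library sizes, named by column or in order.
#' @return Tibble of the same shape with integer counts.
#' @export
#' @examples
#' infer_counts_from_tpm(
#'   tibble::tibble(gene_id = "B2M", brain = 10.9),
#'   c(brain = 92040)
#' ) # 1 read
infer_counts_from_tpm <- function(tpm, library_sizes) {
  parts <- split_expression_table(tpm, library_sizes)
  library_sizes <- match_library_sizes(library_sizes, parts$value_cols)
  if (any(parts$mat < 0)) abort("tpm must be non-negative")
  cnt <- round_half_up(sweep(parts$mat, 2, library_sizes, "*") / 1e6)
  out <- tpm
  out[parts$value_cols] <- as_tibble(matrix(as.integer(cnt), nrow(cnt),
                                            dimnames = dimnames(cnt)))
  out
}
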