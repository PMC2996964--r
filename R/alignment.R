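#' Read tabular BLAST alignments with an e-value cutoff
#'
#' Parses a headerless 12-column tabular alignment file (the BLAST
#' `-outfmt 6` dialect: qseqid, sseqid, pident, length, mismatch, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore). Hits with e-value above the
#' cutoff are dropped; the cutoff is inclusive (`evalue <= cutoff` is kept),
#' the usual convention for BLAST e-value filters. Subject spans with
#' `sstart > send` (minus-strand hits) are normalised so that start <= end and
#' flagged in `sstrand`. Lines with the wrong number of fields are dropped
#' with a warning naming their line numbers; a non-numeric e-value is an
#' error.
#'
#' @param path Path to the tabular alignment file.
#' @param evalue_cutoff Maximum e-value retained (inclusive). Default `1e-10`.
#' @return Tibble with the 12 standard columns plus `sstrand`
#'   (`"plus"`/`"minus"`).
#' @export
read_blast_tabular <- function(path, evalue_cutoff = 1e-10) {
  if (!file.exists(path)) abort(paste0("cannot read alignment file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12)
  if (length(bad) > 0) {
    warn(paste0("dropping ", length(bad), " malformed line(s) (expected 12 ",
                "tab-separated fields): line ", paste(bad, collapse = ", ")))
    fields <- fields[-bad]
  }
  if (length(fields) == 0) {
    return(empty_hits())
  }
  m <- do.call(rbind, fields)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  if (anyNA(evalue)) {
    abort(paste0("non-numeric e-value field on line ",
                 paste(which(is.na(evalue)), collapse = ", ")))
  }
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  hits <- tibble(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = num(3), length = as.integer(num(4)),
    mismatch = as.integer(num(5)), gapopen = as.integer(num(6)),
    qstart = as.integer(num(7)), qend = as.integer(num(8)),
    sstart = as.integer(num(9)), send = as.integer(num(10)),
    evalue = evalue, bitscore = num(12)
  )
  if (any(!is.finite(hits$length)) || any(hits$length <= 0)) {
    abort("alignment length must be a positive number")
  }
  hits <- hits |>
    mutate(
      sstrand = ifelse(.data$sstart > .data$send, "minus", "plus"),
      sstart0 = pmin(.data$sstart, .data$send),
      send = pmax(.data$sstart, .data$send),
      sstart = .data$sstart0
    ) |>
    select(-"sstart0") |>
    filter(.data$evalue <= evalue_cutoff)
  hits
}

empty_hits <- function() {
  tibble(
    qseqid = character(), sseqid = character(), pident = numeric(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = numeric(), bitscore = numeric(),
    sstrand = character()
  )
}

#' Select the best hit per query
#'
#' Applies the best-hit rule: minimum e-value, ties broken by maximum aligned
#' length, remaining ties by lexicographic subject id (so the result is a
#' total, deterministic, permutation-invariant function of the hit list).
#'
#' @param hits Hit tibble as returned by [read_blast_tabular()].
#' @return One-row-per-query tibble of gene assignments: `contig_id`,
#'   `gene_id`, `evalue`, `aligned_length`, plus the remaining hit columns.
#' @export
select_best_hits <- function(hits) {
  if (nrow(hits) == 0) abort("empty hit list")
  hits |>
    arrange(.data$qseqid, .data$evalue, desc(.data$length), .data$sseqid) |>
    distinct(.data$qseqid, .keep_all = TRUE) |>
    transmute(
      contig_id = .data$qseqid, gene_id = .data$sseqid,
      evalue = .data$evalue, aligned_length = .data$length,
      pident = .data$pident, qstart = .data$qstart, qend = .data$qend,
      sstart = .data$sstart, send = .data$send, sstrand = .data$sstrand
    )
}

#' Partition assignments into clean and contaminant sets
#'
#' Contigs whose best hit is to a subject in the contaminant set (for example
#' a foreign-taxon reference identified post hoc) are removed from downstream
#' analysis and returned in a removal report.
#'
#' @param assignments Tibble from [select_best_hits()].
#' @param contaminant_subjects Character vector of contaminant subject ids
#'   (may be empty).
#' @return List with `assignments` (clean tibble) and `removed` (report
#'   tibble: `contig_id`, `gene_id`, `evalue`, `aligned_length`).
#' @export
flag_contaminants <- function(assignments, contaminant_subjects = character()) {
  is_cont <- assignments$gene_id %in% contaminant_subjects
  list(
    assignments = assignments[!is_cont, , drop = FALSE],
    removed = assignments[is_cont, c("contig_id", "gene_id", "evalue",
                                     "aligned_length")]
  )
}

#' Gene coverage from assigned contig lengths
#'
#' Coverage is the summed length of the contigs assigned to a gene divided by
#' the gene (transcript) length, as a percentage, capped at 100 when
#' overlapping contigs push the sum past the gene length.
#'
#' @param gene_length Gene/transcript length in bp (positive scalar).
#' @param contig_lengths Lengths of the contigs assigned to the gene (bp).
#' @return Coverage percentage in `(0, 100]`.
#' @export
#' @examples
#' compute_gene_coverage(1000, c(300, 200)) # 50
#' compute_gene_coverage(1000, c(700, 500)) # capped at 100
compute_gene_coverage <- function(gene_length, contig_lengths) {
  if (length(gene_length) != 1 || !is.finite(gene_length) || gene_length <= 0) {
    abort("gene_length must be a single positive number")
  }
  if (length(contig_lengths) == 0 || any(contig_lengths <= 0)) {
    abort("at least one positive contig length is required")
  }
  min(100, 100 * sum(contig_lengths) / gene_length)
}

#' Per-gene coverage table
#'
#' Data-frame wrapper around [compute_gene_coverage()]: joins assignments to
#' contig and gene lengths and reports, per gene, the number of contigs, the
#' summed contig length, and the capped coverage percentage.
#'
#' @param assignments Clean assignment tibble (`contig_id`, `gene_id`).
#' @param contig_lengths Tibble with `contig_id` and `length` columns.
#' @param gene_lengths Tibble with `gene_id` and `length_bp` columns.
#' @return Tibble: `gene_id`, `n_contigs`, `contig_bp`, `coverage_pct`.
#' @export
summarize_gene_coverage <- function(assignments, contig_lengths, gene_lengths) {
  assignments |>
    inner_join(contig_lengths |> select("contig_id", "length"),
               by = "contig_id") |>
    group_by(.data$gene_id) |>
    summarise(n_contigs = n(), contig_bp = sum(.data$length),
              .groups = "drop") |>
    inner_join(gene_lengths |> select("gene_id", "length_bp"),
               by = "gene_id") |>
    mutate(coverage_pct = pmin(100, 100 * .data$contig_bp / .data$length_bp)) |>
    select("gene_id", "n_contigs", "contig_bp", "coverage_pct")
}

#' Detect splice-suggestive gaps between aligned segments
#'
#' Given the aligned segments of one query on one reference (1-based inclusive
#' reference coordinates), flags the pair as a putative splice variant if any
#' inter-segment distance on the reference strictly exceeds `min_gap` bases.
#' The same rule serves read-versus-contig comparisons (contigs assembling
#' multiple isoforms) and contig-versus-gene-model comparisons (novel
#' isoforms). Overlapping segments are reported in the result, not silently
#' merged.
#'
#' @param segments Two-column matrix or data frame of segment `start`, `end`
#'   positions (1-based inclusive).
#' @param min_gap Gap length that must be strictly exceeded. Default 15.
#' @return List with `flag` (logical), `gaps` (tibble: `gap_start`, `gap_end`,
#'   `width`), `overlaps` (tibble of overlapping segment index pairs).
#' @export
#' @examples
#' detect_alignment_gaps(rbind(c(1, 50), c(66, 120)))$flag # gap of 15: FALSE
#' detect_alignment_gaps(rbind(c(1, 50), c(67, 120)))$flag # gap of 16: TRUE
detect_alignment_gaps <- function(segments, min_gap = 15) {
  seg <- as.matrix(as.data.frame(segments))[, 1:2, drop = FALSE]
  if (nrow(seg) == 0) abort("at least one aligned segment is required")
  if (any(seg[, 1] > seg[, 2])) abort("segment start must be <= end")
  seg <- seg[order(seg[, 1], seg[, 2]), , drop = FALSE]
  gaps <- tibble(gap_start = integer(), gap_end = integer(), width = integer())
  overlaps <- tibble(first = integer(), second = integer())
  if (nrow(seg) > 1) {
    d <- seg[-1, 1] - seg[-nrow(seg), 2] - 1L
    ov <- which(d < 0)
    if (length(ov) > 0) {
      warn(paste0(length(ov), " overlapping segment pair(s) found"))
      overlaps <- tibble(first = ov, second = ov + 1L)
    }
    gp <- which(d > 0)
    gaps <- tibble(
      gap_start = as.integer(seg[gp, 2] + 1L),
      gap_end = as.integer(seg[gp + 1L, 1] - 1L),
      width = as.integer(d[gp])
    )
  }
  list(flag = any(gaps$width > min_gap), gaps = gaps, overlaps = overlaps)
}

#' Flag putative splice variants across a hit table
#'
#' Groups alignment hits by query/subject pair and applies
#' [detect_alignment_gaps()] to the subject spans of each group.
#'
#' @param hits Hit tibble from [read_blast_tabular()].
#' @param min_gap Gap length that must be strictly exceeded. Default 15.
#' @return Tibble: `qseqid`, `sseqid`, `n_segments`, `max_gap`, `splice_flag`.
#' @export
flag_splice_gaps <- function(hits, min_gap = 15) {
  hits |>
    group_by(.data$qseqid, .data$sseqid) |>
    group_modify(function(d, key) {
      res <- suppressWarnings(
        detect_alignment_gaps(cbind(d$sstart, d$send), min_gap = min_gap)
      )
      tibble(
        n_segments = nrow(d),
        max_gap = if (nrow(res$gaps) > 0) max(res$gaps$width) else 0L,
        splice_flag = res$flag
      )
    }) |>
    ungroup()
}

#' Export gaps as BED intervals
#'
#' Converts 1-based inclusive gap coordinates to the 0-based half-open BED
#' convention.
#'
#' @param gaps Tibble with `gap_start`, `gap_end` (1-based inclusive) and a
#'   reference name column `sseqid` (or supply `chrom`).
#' @param chrom Reference name(s), recycled; used when `gaps` lacks `sseqid`.
#' @return Tibble: `chrom`, `start` (0-based), `end` (exclusive).
#' @export
gaps_to_bed <- function(gaps, chrom = NULL) {
  chrom <- chrom %||% gaps$sseqid
  if (is.null(chrom)) abort("supply `chrom` or a `sseqid` column")
  tibble(
    chrom = chrom,
    start = as.integer(gaps$gap_start - 1L),
    end = as.integer(gaps$gap_end)
  )
}
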