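#' The tau index of tissue specificity
#'
#' Computes tau from a TPM profile over `N >= 2` tissues. Tissues with no
#' detected expression (TPM exactly 0) are floored at `floor_tpm` (default 2
#' TPM) before the log transform; positive TPM values enter unfloored. With
#' `x_i = log2(TPM_i)` and `x_max = max(x_i)`,
#' `tau = sum(1 - x_i / x_max) / (N - 1)`. Tau is 0 when all (floored)
#' values are equal and approaches 1 for single-tissue expression. The log2
#' base and the floor of 2 are pinned by reproduction of published tau values
#' in the test suite.
#'
#' Positive TPM values below 1 (impossible for integer counts at library sizes
#' up to one million reads) would give negative logs and push tau outside
#' `[0, 1]`; such values are clamped to 1 TPM with a warning.
#'
#' @param tpm Numeric vector (one profile) or matrix/data frame with one row
#'   per entity and one column per tissue.
#' @param floor_tpm TPM assigned to tissues with zero detected expression.
#' @param floor_all If `TRUE`, floor every value below `floor_tpm`, not only
#'   exact zeros. Used for continuous expected-TPM profiles (e.g. simulator
#'   ground truth), where values below the detection floor correspond to
#'   tissues that sampling would record as zero.
#' @return Numeric tau value(s) in `[0, 1]`.
#' @export
#' @examples
#' compute_tau(c(76.1, 182.2, 323.2, 887.5, 241.7, 4060.4, 250.2)) # 0.336
#' compute_tau(c(10.9, 0.0, 45.8, 9.2, 27.7, 896.1, 43.4)) # 0.602
compute_tau <- function(tpm, floor_tpm = 2, floor_all = FALSE) {
  vec <- is.null(dim(tpm))
  m <- if (vec) matrix(as.numeric(tpm), nrow = 1) else as.matrix(tpm)
  if (ncol(m) < 2) abort("tau requires at least 2 tissues")
  if (any(!is.finite(m)) || any(m < 0)) abort("tpm must be finite and non-negative")
  if (floor_all) {
    m[m < floor_tpm] <- floor_tpm
  } else {
    m[m == 0] <- floor_tpm
    if (any(m < 1)) {
      warn("TPM values in (0, 1) clamped to 1 to keep tau within [0, 1]")
      m[m < 1] <- 1
    }
  }
  x <- log2(m)
  xmax <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  tau <- ifelse(xmax > 0, rowSums(1 - x / pmax(xmax, .Machine$double.eps)) /
                  (ncol(x) - 1), 0)
  # rows where all values are equal have tau exactly 0
  flat <- rows_all_equal(x)
  tau[flat] <- 0
  if (vec) tau[[1]] else unname(tau)
}

rows_all_equal <- function(x) {
  i <- seq_len(nrow(x))
  rmax <- x[cbind(i, max.col(x, ties.method = "first"))]
  rmin <- -(-x)[cbind(i, max.col(-x, ties.method = "first"))]
  rmax == rmin
}

#' Apply the minimum-read filter to expression profiles
#'
#' Entities whose reads total 3 or fewer across all tissues are flagged as
#' filtered: their tau (and tissue of maximal expression) are considered too
#' noisy to report. "Fewer than four reads" and "three or fewer reads" are the
#' same rule, implemented once as `total_reads >= min_reads`.
#'
#' @param counts Wide tibble: id column first, one integer count column per
#'   library.
#' @param min_reads Minimum total reads for tau to be reported. Default 4.
#' @return Input tibble plus `total_reads` and logical `retained`.
#' @export
filter_low_reads <- function(counts, min_reads = 4) {
  parts <- split_expression_table(counts)
  counts |>
    mutate(
      total_reads = as.integer(rowSums(parts$mat)),
      retained = .data$total_reads >= min_reads
    )
}

#' Tissue of maximal expression
#'
#' The tissue with the highest read count for each entity; entities below the
#' read filter get none. Ties are broken by the fixed column order of the
#' input table and flagged.
#'
#' @inheritParams filter_low_reads
#' @return Tibble: `entity_id`, `max_tissue` (`NA` when filtered),
#'   `max_tie` (logical).
#' @export
assign_max_tissue <- function(counts, min_reads = 4) {
  parts <- split_expression_table(counts)
  total <- unname(rowSums(parts$mat))
  idx <- max.col(parts$mat, ties.method = "first")
  tie <- vapply(seq_len(nrow(parts$mat)), function(i) {
    sum(parts$mat[i, ] == parts$mat[i, idx[i]]) > 1
  }, logical(1))
  tibble(
    entity_id = as.character(parts$id),
    max_tissue = ifelse(total >= min_reads, parts$value_cols[idx],
                        NA_character_),
    max_tie = ifelse(total >= min_reads, tie, NA)
  )
}

#' Full tau result table for a count table
#'
#' Combines TPM normalisation, the zero-TPM floor, the minimum-read filter and
#' the tissue of maximal expression into the standard per-entity specificity
#' report.
#'
#' @param counts Wide tibble: id column first, one integer count column per
#'   library.
#' @param library_sizes Positive library sizes, named by count column or in
#'   column order.
#' @param min_reads Minimum total reads for tau to be reported. Default 4.
#' @param floor_tpm TPM floor for undetected tissues. Default 2.
#' @return Tibble: `entity_id`, `tau` (`NA` when filtered), `total_reads`,
#'   `max_tissue`, `max_tie`, `n_tissues`.
#' @export
tau_table <- function(counts, library_sizes, min_reads = 4, floor_tpm = 2) {
  parts <- split_expression_table(counts, library_sizes)
  library_sizes <- match_library_sizes(library_sizes, parts$value_cols)
  tpm <- sweep(parts$mat, 2, library_sizes, "/") * 1e6
  total <- as.integer(rowSums(parts$mat))
  tau <- compute_tau(tpm, floor_tpm = floor_tpm)
  mt <- assign_max_tissue(counts, min_reads = min_reads)
  tibble(
    entity_id = as.character(parts$id),
    tau = ifelse(total >= min_reads, tau, NA_real_),
    total_reads = total,
    max_tissue = mt$max_tissue,
    max_tie = mt$max_tie,
    n_tissues = ncol(parts$mat)
  )
}

#' Summarise a tau distribution
#'
#' Histogram, percentile lookup and Sarle's bimodality coefficient for the
#' unfiltered tau values of a [tau_table()] result. The bimodality coefficient
#' `(g1^2 + 1) / (g2 + 3(n-1)^2 / ((n-2)(n-3)))` (sample skewness `g1`, sample
#' excess kurtosis `g2`) exceeds 5/9 for distributions flatter than uniform or
#' bimodal.
#'
#' @param tau_tbl A [tau_table()] result (or any tibble with a `tau` column).
#' @param n_bins Number of equal-width histogram bins over `[0, 1]`.
#' @return A `tau_summary` list: `histogram` (tibble: `lower`, `upper`,
#'   `mid`, `count`), `percentile` (function mapping tau values to percentile
#'   0--100), `bimodality`, `n`.
#' @export
tau_distribution_summary <- function(tau_tbl, n_bins = 20) {
  tau <- tau_tbl$tau[!is.na(tau_tbl$tau)]
  if (length(tau) == 0) abort("no unfiltered tau values")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(tau, breaks, rightmost.closed = TRUE), 1),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  fn <- ecdf(tau)
  n <- length(tau)
  bimod <- if (n > 3 && sd(tau) > 0) {
    g1 <- e1071::skewness(tau, type = 2)
    g2 <- e1071::kurtosis(tau, type = 2)
    (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  } else {
    NA_real_
  }
  structure(
    list(
      histogram = tibble(
        lower = breaks[-length(breaks)], upper = breaks[-1],
        mid = (breaks[-1] + breaks[-length(breaks)]) / 2, count = counts
      ),
      percentile = function(x) 100 * fn(x),
      bimodality = bimod,
      n = n
    ),
    class = "tau_summary"
  )
}
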