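# Internal helpers shared across modules.

# Vectorised multinomial sampler: one draw per row, via the conditional
# binomial decomposition. `sizes` is an integer vector of totals, `prob` an
# n x k matrix of row-wise probabilities (rows need not be normalised).
# Equivalent in distribution to calling stats::rmultinom row by row, but a
# single rbinom call per category; cross-checked against rmultinom in tests.
rmultinom_rows <- function(sizes, prob) {
  prob <- as.matrix(prob)
  n <- length(sizes)
  stopifnot(nrow(prob) == n)
  k <- ncol(prob)
  if (any(prob < 0) || any(!is.finite(prob))) {
    abort("probability matrix must be finite and non-negative")
  }
  prob <- prob / rowSums(prob)
  out <- matrix(0L, n, k, dimnames = list(NULL, colnames(prob)))
  remaining <- as.integer(round(sizes))
  ptail <- rep(1, n)
  for (j in seq_len(k - 1L)) {
    pj <- ifelse(ptail > 0, pmin(pmax(prob[, j] / ptail, 0), 1), 0)
    draw <- rbinom(n, remaining, pj)
    out[, j] <- draw
    remaining <- remaining - draw
    ptail <- ptail - prob[, j]
  }
  out[, k] <- remaining
  out
}

# Symmetric Dirichlet draws via normalised gammas; n draws of dimension k.
rdirichlet <- function(n, alpha, k = length(alpha)) {
  if (length(alpha) == 1) alpha <- rep(alpha, k)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  s <- rowSums(g)
  # for very small alpha the gamma draws can all underflow to zero; the
  # limiting Dirichlet is then one-hot on a uniformly chosen category
  zero <- which(s == 0)
  if (length(zero) > 0) {
    g[zero, ] <- 0
    g[cbind(zero, sample.int(k, length(zero), replace = TRUE))] <- 1
    s[zero] <- 1
  }
  g / s
}

# Half-up rounding to the nearest integer (round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

# Run `expr` under a fixed seed when one is supplied, untouched otherwise.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Split a wide expression table into its id column and count matrix, checking
# that the measurement columns match `library_sizes` when names are available.
split_expression_table <- function(tbl, library_sizes = NULL, id_col = NULL) {
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2)
  id_col <- id_col %||% names(tbl)[1]
  value_cols <- setdiff(names(tbl), c(id_col, "length", "length_bp"))
  if (!is.null(library_sizes) && !is.null(names(library_sizes)) &&
      all(names(library_sizes) %in% names(tbl))) {
    value_cols <- names(library_sizes)
  }
  mat <- as.matrix(tbl[value_cols])
  if (!is.numeric(mat)) abort("expression columns must be numeric")
  rownames(mat) <- as.character(tbl[[id_col]])
  list(id = tbl[[id_col]], mat = mat, id_col = id_col, value_cols = value_cols)
}

match_library_sizes <- function(library_sizes, value_cols) {
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    abort("library sizes must be positive and finite")
  }
  if (!is.null(names(library_sizes))) {
    missing <- setdiff(value_cols, names(library_sizes))
    if (length(missing) > 0) {
      abort(paste0("no library size given for: ", paste(missing, collapse = ", ")))
    }
    library_sizes <- library_sizes[value_cols]
  } else if (length(library_sizes) != length(value_cols)) {
    abort("library_sizes length does not match the number of count columns")
  } else {
    names(library_sizes) <- value_cols
  }
  library_sizes
}
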