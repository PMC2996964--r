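#' Select the most and least tissue-specific gene sets
#'
#' Returns the k genes with the highest and the k with the lowest tau among
#' the unfiltered entries; ties at either boundary are broken by gene id so
#' the selection is deterministic.
#'
#' @param tau_tbl A [tau_table()] result.
#' @param k Set size (default 500, the conventional choice for genome-wide
#'   scans of this size).
#' @return List with character vectors `high_tau` and `low_tau`.
#' @export
select_tau_extreme_sets <- function(tau_tbl, k = 500) {
  d <- tau_tbl |> filter(!is.na(.data$tau))
  if (nrow(d) < 2 * k) {
    abort(paste0("need at least ", 2 * k, " unfiltered genes, have ", nrow(d)))
  }
  high <- d |> arrange(desc(.data$tau), .data$entity_id) |> head(k)
  low <- d |> arrange(.data$tau, .data$entity_id) |> head(k)
  list(high_tau = high$entity_id, low_tau = low$entity_id)
}

# Expand a gene_id/go_terms annotation (semicolon-separated or list column)
# into a long gene-term tibble.
expand_go_annotation <- function(annotations) {
  if (is.list(annotations$go_terms)) {
    tibble(
      gene_id = rep(annotations$gene_id, lengths(annotations$go_terms)),
      term_id = unlist(annotations$go_terms, use.names = FALSE)
    )
  } else {
    annotations |>
      select("gene_id", "go_terms") |>
      mutate(go_terms = as.character(.data$go_terms)) |>
      filter(!is.na(.data$go_terms), nzchar(.data$go_terms)) |>
      tidyr::separate_longer_delim("go_terms", delim = ";") |>
      rename(term_id = "go_terms") |>
      filter(nzchar(.data$term_id))
  }
}

#' GO-term overrepresentation by one-sided hypergeometric test
#'
#' For every term annotated in the universe, tests whether the term is more
#' common in the gene set than expected by chance: with X ~
#' Hypergeometric(universe_size, universe_count, set_size), the raw p-value is
#' P[X >= set_count] (one-sided Fisher test for overrepresentation). P-values
#' are adjusted across terms by Benjamini-Hochberg by default. Terms are
#' treated as flat labels; no ontology-graph propagation is performed.
#'
#' @param gene_set Character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of all gene ids under consideration.
#' @param annotations Tibble with `gene_id` and `go_terms` (semicolon-separated
#'   string or list column).
#' @param adjust Multiple-testing adjustment: `"BH"` (default) or
#'   `"bonferroni"`.
#' @param alpha Significance threshold applied to the adjusted p-value.
#' @return Tibble sorted by adjusted p: `term_id`, `set_count`, `set_size`,
#'   `universe_count`, `universe_size`, `p_raw`, `p_adjusted`, `significant`.
#' @export
go_overrepresentation <- function(gene_set, universe, annotations,
                                  adjust = c("BH", "bonferroni"),
                                  alpha = 0.05) {
  adjust <- match.arg(adjust)
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe)) {
    abort("gene_set must be a subset of the universe")
  }
  long <- expand_go_annotation(annotations) |>
    filter(.data$gene_id %in% universe) |>
    distinct()
  terms <- long |>
    group_by(.data$term_id) |>
    summarise(
      universe_count = n(),
      set_count = sum(.data$gene_id %in% gene_set),
      .groups = "drop"
    ) |>
    mutate(
      set_size = length(gene_set),
      universe_size = length(universe),
      p_raw = phyper(.data$set_count - 1, .data$universe_count,
                     .data$universe_size - .data$universe_count,
                     .data$set_size, lower.tail = FALSE),
      p_adjusted = p.adjust(.data$p_raw, method = adjust),
      significant = .data$p_adjusted < alpha
    ) |>
    select("term_id", "set_count", "set_size", "universe_count",
           "universe_size", "p_raw", "p_adjusted", "significant") |>
    arrange(.data$p_adjusted, .data$p_raw, .data$term_id)
  terms
}

#' Correlation between two gene-level variables
#'
#' Pearson or Spearman correlation with optional log transforms, reporting the
#' coefficient, `df = n - 2`, and the p-value. Spearman uses average ranks for
#' ties (and is invariant to any strictly monotone transform of either
#' variable). Pairs with missing or non-finite values (e.g. log of zero) are
#' dropped.
#'
#' @param data A data frame.
#' @param x,y Column names (strings) of the two variables.
#' @param method `"pearson"` or `"spearman"`.
#' @param transform_x,transform_y `"none"`, `"log"` (natural log), `"log10"`,
#'   or `"log1p"`.
#' @return Tibble: `estimate`, `df`, `p.value`, `n`, `method`.
#' @export
#' @examples
#' correlate(data.frame(a = 1:3, b = c(10, 1, 5)), "a", "b",
#'           method = "spearman") # r_s = -0.5
correlate <- function(data, x, y, method = c("pearson", "spearman"),
                      transform_x = c("none", "log", "log10", "log1p"),
                      transform_y = c("none", "log", "log10", "log1p")) {
  method <- match.arg(method)
  fx <- switch(match.arg(transform_x),
               none = identity, log = log, log10 = log10, log1p = log1p)
  fy <- switch(match.arg(transform_y),
               none = identity, log = log, log10 = log10, log1p = log1p)
  xv <- fx(data[[x]])
  yv <- fy(data[[y]])
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 3) abort("need at least 3 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero variance: correlation undefined")
  ct <- suppressWarnings(cor.test(xv, yv, method = method, exact = FALSE))
  tibble(estimate = unname(ct$estimate), df = length(xv) - 2L,
         p.value = ct$p.value, n = length(xv), method = method)
}

#' Compare a variable between groups of genes
#'
#' Kruskal-Wallis (tie-corrected H, `df = groups - 1`) or one-way ANOVA
#' (`df = (groups - 1, n - groups)`), typically applied to omega or tau grouped
#' by the tissue of maximal expression.
#'
#' @param data A data frame.
#' @param value Column name (string) of the response variable.
#' @param group Column name (string) of the grouping variable.
#' @param method `"kruskal"` or `"anova"`.
#' @return Tibble: `statistic`, `df`, `df_resid` (`NA` for Kruskal-Wallis),
#'   `p.value`, `n_groups`, `method`.
#' @export
group_compare <- function(data, value, group, method = c("kruskal", "anova")) {
  method <- match.arg(method)
  keep <- !is.na(data[[value]]) & !is.na(data[[group]])
  v <- data[[value]][keep]
  g <- factor(data[[group]][keep])
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("need at least 2 groups with at least 2 values each")
  }
  if (method == "kruskal") {
    kt <- kruskal.test(v, g)
    tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
           df_resid = NA_integer_, p.value = kt$p.value,
           n_groups = length(sizes), method = method)
  } else {
    fit <- anova(aov(v ~ g))
    tibble(statistic = fit$`F value`[1], df = fit$Df[1],
           df_resid = fit$Df[2], p.value = fit$`Pr(>F)`[1],
           n_groups = length(sizes), method = method)
  }
}

# Percentile bootstrap CI of the mean, chunked to bound memory.
boot_ci_mean <- function(x, n_boot = 10000, conf_level = 0.95) {
  n <- length(x)
  if (n < 3) return(c(NA_real_, NA_real_))
  means <- numeric(n_boot)
  chunk <- max(1L, min(n_boot, as.integer(floor(5e6 / n))))
  done <- 0L
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    m <- matrix(sample(x, n * b, replace = TRUE), nrow = b)
    means[done + seq_len(b)] <- rowMeans(m)
    done <- done + b
  }
  a <- (1 - conf_level) / 2
  unname(quantile(means, c(a, 1 - a)))
}

t_ci_mean <- function(x, conf_level = 0.95) {
  n <- length(x)
  if (n < 3) return(c(NA_real_, NA_real_))
  se <- sd(x) / sqrt(n)
  mean(x) + c(-1, 1) * stats::qt(1 - (1 - conf_level) / 2, n - 1) * se
}

#' Per-tissue summary of omega and tau for maximally expressed genes
#'
#' For each tissue: the number of genes with maximal expression there, the
#' number expressed exclusively there (reads in no other tissue, subject to
#' the read filter), and the means of omega and tau with 95% confidence
#' intervals. Because omega is heavily right-skewed, the default CI is a
#' nonparametric percentile bootstrap (10,000 resamples); a t-interval is
#' available. CIs are `NA` when fewer than 3 genes contribute.
#'
#' @param tau_tbl A [tau_table()] result (gene-level).
#' @param annotations Tibble with `gene_id` and `omega`.
#' @param counts Optional wide gene count tibble, used to count exclusively
#'   expressed genes; `n_exclusive` is `NA` when omitted.
#' @param n_boot Bootstrap resamples. Default 10000.
#' @param conf_level Confidence level. Default 0.95.
#' @param ci `"bootstrap"` (percentile) or `"t"`.
#' @param seed Optional seed for the bootstrap.
#' @return Tibble: `tissue`, `n_max`, `n_exclusive`, `mean_omega`,
#'   `omega_ci_lo`, `omega_ci_hi`, `mean_tau`, `tau_ci_lo`, `tau_ci_hi`.
#' @export
summarize_by_max_tissue <- function(tau_tbl, annotations, counts = NULL,
                                    n_boot = 10000, conf_level = 0.95,
                                    ci = c("bootstrap", "t"), seed = NULL) {
  ci <- match.arg(ci)
  ci_fun <- if (ci == "bootstrap") {
    function(x) boot_ci_mean(x, n_boot, conf_level)
  } else {
    function(x) t_ci_mean(x, conf_level)
  }
  d <- tau_tbl |>
    filter(!is.na(.data$max_tissue)) |>
    left_join(annotations |> select("gene_id", "omega"),
              by = c(entity_id = "gene_id"))
  excl <- NULL
  if (!is.null(counts)) {
    parts <- split_expression_table(counts)
    one_tissue <- rowSums(parts$mat > 0) == 1
    tot_ok <- rowSums(parts$mat) >= 4
    idx <- which(one_tissue & tot_ok)
    excl_tissue <- parts$value_cols[max.col(parts$mat[idx, , drop = FALSE],
                                            ties.method = "first")]
    excl <- tibble(tissue = excl_tissue) |> count(.data$tissue,
                                                  name = "n_exclusive")
  }
  out <- with_seed_if(seed, {
    d |>
      group_by(tissue = .data$max_tissue) |>
      group_modify(function(g, key) {
        om <- g$omega[!is.na(g$omega)]
        ta <- g$tau[!is.na(g$tau)]
        oc <- ci_fun(om)
        tc <- ci_fun(ta)
        tibble(
          n_max = nrow(g),
          mean_omega = if (length(om)) mean(om) else NA_real_,
          omega_ci_lo = oc[1], omega_ci_hi = oc[2],
          mean_tau = if (length(ta)) mean(ta) else NA_real_,
          tau_ci_lo = tc[1], tau_ci_hi = tc[2]
        )
      }) |>
      ungroup()
  })
  if (!is.null(excl)) {
    out <- out |> left_join(excl, by = "tissue") |>
      mutate(n_exclusive = tidyr::replace_na(.data$n_exclusive, 0L))
  } else {
    out$n_exclusive <- NA_integer_
  }
  out |> select("tissue", "n_max", "n_exclusive", everything())
}
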