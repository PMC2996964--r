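#' Histogram of a tau distribution
#'
#' @param tau_tbl A [tau_table()] result.
#' @param n_bins Number of bins over `[0, 1]`.
#' @return A ggplot object.
#' @export
plot_tau_distribution <- function(tau_tbl, n_bins = 20) {
  s <- tau_distribution_summary(tau_tbl, n_bins = n_bins)
  ggplot2::ggplot(s$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 1 / n_bins, fill = "grey35") +
    ggplot2::labs(
      x = expression(tau), y = "entities",
      subtitle = sprintf("n = %d, bimodality coefficient = %.3f",
                         s$n, s$bimodality)
    ) +
    ggplot2::theme_minimal()
}

#' Total expression versus tissue specificity
#'
#' Scatter of tau against log10 total reads for all unfiltered entities, the
#' relationship whose negative trend motivates the resampling null.
#'
#' @param tau_tbl A [tau_table()] result.
#' @return A ggplot object.
#' @export
plot_expression_specificity <- function(tau_tbl) {
  d <- tau_tbl |> filter(!is.na(.data$tau))
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$total_reads),
                                  y = .data$tau)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick",
                         se = FALSE) +
    ggplot2::labs(x = "log10 total reads", y = expression(tau)) +
    ggplot2::theme_minimal()
}

#' Tissue specificity versus molecular evolutionary rate
#'
#' Scatter of log(omega + 1) against tau for genes with both values, the
#' expression-breadth versus dN/dS relationship.
#'
#' @param tau_tbl A gene-level [tau_table()] result.
#' @param annotations Tibble with `gene_id` and `omega`.
#' @return A ggplot object.
#' @export
plot_specificity_omega <- function(tau_tbl, annotations) {
  d <- tau_tbl |>
    filter(!is.na(.data$tau)) |>
    inner_join(annotations |> select("gene_id", "omega"),
               by = c(entity_id = "gene_id")) |>
    filter(!is.na(.data$omega))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau, y = log(.data$omega + 1))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick",
                         se = FALSE) +
    ggplot2::labs(x = expression(tau), y = "log(ω + 1)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bias_sim <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$simulated_r)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$observed$estimate,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$comparison$mean_simulated_r,
                        colour = "steelblue", linetype = 2) +
    ggplot2::labs(
      x = "simulated correlation (null)", y = "datasets",
      subtitle = sprintf(
        "observed r = %.3f (red), mean simulated r = %.3f (blue), t = %.2f, df = %d",
        object$observed$estimate, object$comparison$mean_simulated_r,
        object$comparison$t_statistic, object$comparison$df
      )
    ) +
    ggplot2::theme_minimal()
}
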