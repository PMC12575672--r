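# ggplot2 displays for the main result types.

#' Plot a replication-probability curve
#'
#' Replication probability against per-half sample size, with the
#' replicability threshold as a dashed reference line. Undefined
#' probabilities (no discovery-significant shuffle) are omitted.
#'
#' @param object A `replication_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.replication_curve <- function(object, ...) {
  d <- object$summary[!is.na(object$summary$p_replicability), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$p_replicability)) +
    ggplot2::geom_hline(
      yintercept = object$threshold,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "per-half sample size n", y = "P(replicability)",
      title = sprintf("%s / %s", object$phenotype, object$metric)
    ) +
    ggplot2::theme_minimal()
}

#' Plot every curve of an experiment as a replicability heatmap
#'
#' Phenotype-by-sample-size tile map of replication probability, the data
#' behind the usual replicability heatmap figure.
#'
#' @param object A `replication_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.replication_experiment <- function(object, ...) {
  d <- object$curve_summary
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$n), y = .data$phenotype, fill = .data$p_replicability
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(
      x = "per-half sample size n", y = NULL, fill = "P(replicability)"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of empirical vs theoretical minimum sample sizes
#'
#' @param comparison Tibble with `n_E` and `n_T` columns (e.g. the
#'   `comparison` element of a `replication_experiment`).
#' @return A ggplot with the identity line for reference.
#' @export
plot_empirical_theoretical <- function(comparison) {
  d <- comparison[is.finite(comparison$n_E) & is.finite(comparison$n_T), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_E, y = .data$n_T)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "empirical minimum replicable n (n_E)",
      y = "theoretical required n (n_T)"
    ) +
    ggplot2::theme_minimal()
}
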