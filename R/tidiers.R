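# broom-style tidiers.

#' Tidy a nested cross-validation fit
#'
#' @param x A `nested_cv_fit`.
#' @param ... Unused.
#' @return The pooled out-of-fold predictions as a tibble
#'   (`subject_id`, `y`, `yhat`, `outer_fold`).
#' @export
tidy.nested_cv_fit <- function(x, ...) {
  x$oof
}

#' @rdname tidy.nested_cv_fit
#' @return `glance()` returns a one-row tibble with `r_dis`, `p_dis`,
#'   `selected_alpha`, `n`, `n_outer`, `n_inner`.
#' @export
glance.nested_cv_fit <- function(x, ...) {
  tibble::tibble(
    r_dis = x$r_dis, p_dis = x$p_dis, selected_alpha = x$selected_alpha,
    n = nrow(x$oof), n_outer = x$n_outer, n_inner = x$n_inner
  )
}

#' Tidy a replication curve
#'
#' @param x A `replication_curve`.
#' @param ... Unused.
#' @return `tidy()` returns the per-sample-size summary (one row per `n`,
#'   with `p_replicability`, mean effect sizes and `delta_r`); `glance()`
#'   returns a one-row overview including the minimum replicable sample size
#'   `n_E`.
#' @export
tidy.replication_curve <- function(x, ...) {
  dplyr::mutate(x$summary, phenotype = x$phenotype, metric = x$metric, .before = 1)
}

#' @rdname tidy.replication_curve
#' @export
glance.replication_curve <- function(x, ...) {
  tibble::tibble(
    phenotype = x$phenotype, metric = x$metric,
    n_E = x$n_E,
    max_p_replicability = suppressWarnings(
      max(x$summary$p_replicability, na.rm = TRUE)
    ),
    n_shuffles = x$n_shuffles, alpha = x$alpha, threshold = x$threshold
  )
}

#' Tidy a replication experiment
#'
#' @param x A `replication_experiment`.
#' @param ... Unused.
#' @return `tidy()` returns the per-curve, per-n summary table; `glance()`
#'   one row with curve counts and the empirical-theoretical correlation.
#' @export
tidy.replication_experiment <- function(x, ...) {
  x$curve_summary
}

#' @rdname tidy.replication_experiment
#' @export
glance.replication_experiment <- function(x, ...) {
  tibble::tibble(
    n_curves = length(x$curves),
    n_phenotypes = length(unique(x$records$phenotype)),
    n_replicable = sum(is.finite(x$comparison$n_E)),
    comparison_correlation = x$comparison_correlation
  )
}
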