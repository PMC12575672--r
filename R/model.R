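# Nested cross-validated ridge on a discovery sample, refit-and-evaluate on a
# replication sample, and the correlation significance test both stages share.

#' Default ridge penalty grid
#'
#' Thirteen log-spaced penalties from 1e-3 to 1e5 — wide enough to span
#' near-OLS fits at one end and shrink-to-null at the other, so the inner
#' loop can always express "no predictable signal" by picking a huge penalty.
#'
#' @return Numeric vector of length 13, ascending.
#' @export
default_alpha_grid <- function() {
  10^seq(-3, 5, length.out = 13)
}

#' Pearson correlation and its t-based p-value
#'
#' The significance test used for both the discovery association (observed
#' target vs pooled out-of-fold prediction) and the replication association
#' (observed target vs refit-model prediction). The default is one-sided in
#' the positive direction, because only a positive prediction-observation
#' correlation indicates predictive skill; a model whose predictions
#' anti-correlate with the target has not learned the phenotype.
#'
#' @param y,yhat Numeric vectors of equal length (>= 3).
#' @param sided `"one"` (positive association, default) or `"two"`.
#' @return A list with `r` and `p`. Constant input yields `r = NA`, `p = 1`.
#' @examples
#' corr_pvalue(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
corr_pvalue <- function(y, yhat, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(length(y) == length(yhat))
  n <- length(y)
  if (n < 3) abort("corr_pvalue() needs at least 3 pairs")
  if (sd(y) == 0 || sd(yhat) == 0) {
    return(list(r = NA_real_, p = 1))
  }
  r <- cor(y, yhat)
  df <- n - 2
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- if (sided == "one") {
    pt(tt, df, lower.tail = FALSE)
  } else {
    2 * pt(abs(tt), df, lower.tail = FALSE)
  }
  list(r = r, p = min(max(p, 0), 1))
}

make_folds <- function(n, k) {
  sample(rep_len(seq_len(k), n))
}

# Inner-loop penalty selection across inner folds, ties broken toward the
# largest penalty (more regularization). The default score is held-out
# predictive R^2 (1 - SSE/SST): unlike correlation it is not scale-invariant,
# so an interpolating near-zero penalty whose predictions have wildly
# inflated variance scores badly instead of tying with well-shrunk fits.
select_alpha <- function(X, y, n_inner, alpha_grid, score = "r2") {
  folds <- make_folds(nrow(X), n_inner)
  scores <- matrix(NA_real_, n_inner, length(alpha_grid))
  for (f in seq_len(n_inner)) {
    tr <- folds != f
    yte <- y[!tr]
    if (length(yte) < 2 || sd(y[tr]) == 0 || sd(yte) == 0) next
    fit <- ridge_path(X[tr, , drop = FALSE], y[tr], alpha_grid)
    pred <- predict_ridge_path(fit, X[!tr, , drop = FALSE])
    scores[f, ] <- if (score == "r2") {
      1 - colMeans((pred - yte)^2) / mean((yte - mean(yte))^2)
    } else {
      apply(pred, 2, safe_cor, y = yte)
    }
  }
  m <- colMeans(scores, na.rm = TRUE)
  m[is.nan(m) | is.na(m)] <- -Inf
  best <- max(which(m >= max(m)))
  list(alpha = alpha_grid[best], mean_score = m[best], scores = m)
}

#' Fit a ridge model under nested cross-validation
#'
#' The discovery-stage model fit. An outer 5-fold loop produces one
#' out-of-fold prediction per subject; within each outer training partition an
#' inner 5-fold loop selects the ridge penalty by held-out predictive R^2.
#' The discovery effect size `r_dis` is the Pearson correlation between the
#' observed target and the pooled out-of-fold predictions. Because each outer
#' fold's model has its own intercept and output scale, raw pooling is a
#' biased, unstable correlation estimator (fold means of the predictions are
#' anti-correlated with the held-out fold means); by default each fold's
#' predictions are therefore centered before pooling, which removes the
#' intercept bias and restores null calibration of the discovery p-value
#' while leaving each fold's output scale (its share of the pooled variance)
#' untouched. `pooling = "fold-standardized"` additionally equalizes fold
#' scales (this over-weights weak folds and inflates the null variance of
#' the pooled correlation — the fold estimates are positively dependent — so
#' it is not the default); `pooling = "raw"` pools untouched predictions.
#' Feature standardization is always computed on training partitions only.
#'
#' @param features Feature table (tibble with `subject_id` first column), data
#'   frame, or numeric matrix.
#' @param y Numeric target vector aligned with `features`, or a phenotype
#'   table (`subject_id`, value) to be matched by id.
#' @param n_outer,n_inner Outer / inner fold counts (default 5 and 5).
#' @param alpha_grid Ridge penalty grid (default [default_alpha_grid()]).
#' @param seed Optional integer seed controlling the fold draws; the caller's
#'   RNG state is left untouched.
#' @param sided Sidedness of the discovery p-value (see [corr_pvalue()]).
#' @param inner_score Inner-loop selection score: `"r2"` (held-out predictive
#'   R^2, default) or `"cor"` (held-out correlation; scale-blind, kept for
#'   comparison).
#' @param pooling `"fold-centered"` (default), `"fold-standardized"` or
#'   `"raw"` treatment of out-of-fold predictions before pooling; see
#'   Details.
#' @param keep_models Keep the per-outer-fold ridge fits (needed only for the
#'   `"outer-ensemble-mean"` replication strategy). Default `FALSE`.
#' @return An object of class `nested_cv_fit`: `r_dis`, `p_dis`,
#'   `selected_alpha` (penalty re-selected by inner-style CV on the full
#'   discovery sample, used for the replication refit), `oof` (tibble of
#'   pooled out-of-fold predictions), `outer` (per-fold selected penalties).
#' @examples
#' X <- matrix(rnorm(200 * 10), 200, 10)
#' y <- X[, 1] - X[, 2] + rnorm(200, sd = 0.1)
#' fit <- fit_nested_cv(X, y, seed = 1)
#' glance(fit)
#' @export
fit_nested_cv <- function(features, y,
                          n_outer = 5, n_inner = 5,
                          alpha_grid = default_alpha_grid(),
                          seed = NULL,
                          sided = c("one", "two"),
                          inner_score = c("r2", "cor"),
                          pooling = c("fold-centered", "fold-standardized", "raw"),
                          keep_models = FALSE) {
  sided <- match.arg(sided)
  inner_score <- match.arg(inner_score)
  pooling <- match.arg(pooling)
  fm <- as_feature_matrix(features)
  yv <- as_response(y, fm$ids)
  n <- nrow(fm$X)
  if (n < 2 * n_outer) {
    abort(sprintf("need at least %d subjects for %d outer folds", 2 * n_outer, n_outer))
  }
  if (sd(yv) == 0) abort("degenerate target: y is constant")
  alpha_grid <- sort(alpha_grid)

  res <- with_local_seed(seed, {
    outer_folds <- make_folds(n, n_outer)
    oof <- rep(NA_real_, n)
    outer_alpha <- numeric(n_outer)
    outer_models <- if (keep_models) vector("list", n_outer) else NULL
    for (f in seq_len(n_outer)) {
      tr <- outer_folds != f
      sel <- select_alpha(
        fm$X[tr, , drop = FALSE], yv[tr], n_inner, alpha_grid,
        score = inner_score
      )
      fit <- ridge_path(fm$X[tr, , drop = FALSE], yv[tr], sel$alpha)
      oof[!tr] <- predict_ridge_path(fit, fm$X[!tr, , drop = FALSE])[, 1]
      outer_alpha[f] <- sel$alpha
      if (keep_models) outer_models[[f]] <- fit
    }
    # Penalty for the eventual replication refit, re-selected on the full
    # discovery sample with the same inner-CV procedure.
    final <- select_alpha(fm$X, yv, n_inner, alpha_grid, score = inner_score)
    list(
      outer_folds = outer_folds, oof = oof, outer_alpha = outer_alpha,
      selected_alpha = final$alpha, outer_models = outer_models
    )
  })

  pooled <- res$oof
  if (pooling != "raw") {
    for (f in seq_len(n_outer)) {
      idx <- res$outer_folds == f
      pooled[idx] <- pooled[idx] - mean(pooled[idx])
      if (pooling == "fold-standardized") {
        s_f <- sd(pooled[idx])
        pooled[idx] <- if (is.na(s_f) || s_f == 0) 0 else pooled[idx] / s_f
      }
    }
  }
  ct <- corr_pvalue(yv, pooled, sided = sided)
  structure(
    list(
      r_dis = ct$r, p_dis = ct$p,
      selected_alpha = res$selected_alpha,
      oof = tibble::tibble(
        subject_id = fm$ids, y = yv, yhat = res$oof,
        yhat_pooled = pooled, outer_fold = res$outer_folds
      ),
      outer = tibble::tibble(
        fold = seq_len(n_outer), alpha = res$outer_alpha
      ),
      alpha_grid = alpha_grid, n_outer = n_outer, n_inner = n_inner,
      sided = sided, inner_score = inner_score, pooling = pooling, seed = seed,
      outer_models = res$outer_models
    ),
    class = "nested_cv_fit"
  )
}

#' @export
print.nested_cv_fit <- function(x, ...) {
  cat(sprintf(
    "<nested_cv_fit> n = %d: r_dis = %.3f (p = %.2g), alpha = %g\n",
    nrow(x$oof), x$r_dis, x$p_dis, x$selected_alpha
  ))
  invisible(x)
}

#' Refit on the full discovery sample and evaluate on the replication sample
#'
#' The replication stage: one ridge model is refit on the whole discovery
#' sample at the inner-CV-selected penalty (standardization parameters from
#' the discovery sample only) and applied to the held-out replication sample;
#' `r_rep` is the Pearson correlation between observed and predicted
#' replication targets. The alternative `"outer-ensemble-mean"` strategy
#' averages the predictions of the outer-loop models instead (requires a
#' `nested_cv_fit` built with `keep_models = TRUE`).
#'
#' @param features_dis,y_dis Discovery features and target.
#' @param selected_alpha Ridge penalty (or a `nested_cv_fit`, from which the
#'   penalty — and, for the ensemble strategy, the outer models — are taken).
#' @param features_rep,y_rep Replication features and target; replication
#'   subjects must be disjoint from discovery subjects.
#' @param sided Sidedness of the replication p-value.
#' @param strategy `"refit"` (default) or `"outer-ensemble-mean"`.
#' @return A list with `r_rep`, `p_rep`, `predictions` (tibble) and
#'   `coefficients` (edge-weight vector of the refit model; `NULL` for the
#'   ensemble strategy).
#' @export
refit_and_evaluate <- function(features_dis, y_dis, selected_alpha,
                               features_rep, y_rep,
                               sided = c("one", "two"),
                               strategy = c("refit", "outer-ensemble-mean")) {
  sided <- match.arg(sided)
  strategy <- match.arg(strategy)
  fit_obj <- NULL
  if (inherits(selected_alpha, "nested_cv_fit")) {
    fit_obj <- selected_alpha
    selected_alpha <- fit_obj$selected_alpha
  }
  dm <- as_feature_matrix(features_dis)
  rm_ <- as_feature_matrix(features_rep)
  has_ids <- function(x) {
    (is.data.frame(x) && "subject_id" %in% names(x)) ||
      (is.matrix(x) && !is.null(rownames(x)))
  }
  if (has_ids(features_dis) && has_ids(features_rep) &&
    length(intersect(dm$ids, rm_$ids)) > 0) {
    abort("protocol error: discovery and replication subjects overlap")
  }
  ydv <- as_response(y_dis, dm$ids)
  yrv <- as_response(y_rep, rm_$ids)

  if (strategy == "refit") {
    fit <- ridge_path(dm$X, ydv, selected_alpha)
    pred <- predict_ridge_path(fit, rm_$X)[, 1]
    coefs <- ridge_coefficients(fit, selected_alpha)$coefficients
  } else {
    if (is.null(fit_obj) || is.null(fit_obj$outer_models)) {
      abort("outer-ensemble-mean needs a nested_cv_fit built with keep_models = TRUE")
    }
    preds <- vapply(
      fit_obj$outer_models,
      function(f) predict_ridge_path(f, rm_$X)[, 1],
      numeric(nrow(rm_$X))
    )
    pred <- rowMeans(preds)
    coefs <- NULL
  }
  ct <- corr_pvalue(yrv, pred, sided = sided)
  list(
    r_rep = ct$r, p_rep = ct$p,
    predictions = tibble::tibble(subject_id = rm_$ids, y = yrv, yhat = pred),
    coefficients = coefs
  )
}
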