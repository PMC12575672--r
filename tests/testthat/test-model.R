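test_that("corr_pvalue matches the t transform and cor.test", {
  set.seed(21)
  for (i in 1:5) {
    pair <- make_gaussian_pair(30 + 10 * i, 0.3)
    ours2 <- corr_pvalue(pair$x, pair$y, sided = "two")
    ref2 <- cor.test(pair$x, pair$y)
    expect_equal(ours2$r, unname(ref2$estimate), tolerance = 1e-12)
    expect_equal(ours2$p, ref2$p.value, tolerance = 1e-10)

    ours1 <- corr_pvalue(pair$x, pair$y, sided = "one")
    ref1 <- cor.test(pair$x, pair$y, alternative = "greater")
    expect_equal(ours1$p, ref1$p.value, tolerance = 1e-10)
  }

  # r = 0.5 at n = 27: t = 2.8868, two-sided p ~= 0.0079
  z <- make_gaussian_pair(27, 0)
  x <- scale(z$x)[, 1]
  e <- resid(lm(z$y ~ x))
  e <- scale(e)[, 1]
  y_exact <- 0.5 * x + sqrt(1 - 0.25) * e
  out <- corr_pvalue(x, y_exact, sided = "two")
  expect_equal(out$r, 0.5, tolerance = 1e-10)
  expect_equal(out$p, 2 * pt(2.8868, 25, lower.tail = FALSE), tolerance = 1e-3)
})

test_that("corr_pvalue honors the positive-association convention and degenerate input", {
  y <- rnorm(50)
  expect_lt(corr_pvalue(y, y + rnorm(50, sd = 1e-6))$p, 1e-20)
  expect_gt(corr_pvalue(y, -y, sided = "one")$p, 0.999)
  out <- corr_pvalue(y, rep(1, 50))
  expect_true(is.na(out$r))
  expect_equal(out$p, 1)
  expect_error(corr_pvalue(1:2, 2:1), "at least 3")
})

test_that("closed-form ridge path matches the normal equations and glmnet", {
  set.seed(5)
  n <- 80
  p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] - 2 * X[, 2] + rnorm(n)
  lambdas <- c(0.5, 5, 50)
  fit <- repliconn:::ridge_path(X, y, lambdas)
  Xs <- scale(X)
  # exact oracle: ridge normal equations on the standardized design
  for (j in seq_along(lambdas)) {
    direct <- solve(
      crossprod(Xs) + lambdas[j] * diag(p),
      crossprod(Xs, y - mean(y))
    )
    expect_equal(unname(fit$beta[, j]), as.numeric(direct), tolerance = 1e-10)
  }
  # independent implementation: glmnet (its lambda is scaled by n and by the
  # response standard deviation)
  skip_if_not_installed("glmnet")
  for (j in seq_along(lambdas)) {
    g <- glmnet::glmnet(Xs, y,
      alpha = 0, lambda = lambdas[j] / n * sd(y),
      standardize = FALSE, intercept = TRUE, thresh = 1e-14
    )
    expect_equal(
      unname(fit$beta[, j]),
      as.numeric(g$beta),
      tolerance = 1e-2
    )
  }
})

test_that("ridge predictions use training-set standardization only", {
  set.seed(6)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- X[, 1] + rnorm(50, sd = 0.1)
  fit <- repliconn:::ridge_path(X, y, 1)
  Xnew <- matrix(rnorm(10 * 4, mean = 5), 10, 4) # shifted covariates
  pred <- repliconn:::predict_ridge_path(fit, Xnew)
  manual <- sweep(sweep(Xnew, 2, fit$center), 2, fit$scale, "/") %*% fit$beta + fit$intercept
  expect_equal(pred, manual)
  cf <- repliconn:::ridge_coefficients(fit, 1)
  expect_equal(
    as.numeric(Xnew %*% cf$coefficients + cf$intercept),
    as.numeric(pred)
  )
})

test_that("nested CV recovers a noiseless linear signal", {
  set.seed(31)
  d <- make_linear_dataset(200, 20, k = 5, noise = 0)
  fit <- fit_nested_cv(d$X, d$y, seed = 1)
  expect_gt(fit$r_dis, 0.95)
  expect_lt(fit$p_dis, 1e-6)
  expect_equal(nrow(tidy(fit)), 200)
  expect_false(anyNA(tidy(fit)$yhat))
})

test_that("nested CV is deterministic in its seed and folds differ across seeds", {
  set.seed(32)
  d <- make_linear_dataset(60, 10, noise = 1)
  f1 <- fit_nested_cv(d$X, d$y, seed = 7)
  f2 <- fit_nested_cv(d$X, d$y, seed = 7)
  expect_identical(glance(f1), glance(f2))
  expect_identical(tidy(f1), tidy(f2))
  f3 <- fit_nested_cv(d$X, d$y, seed = 8)
  expect_false(identical(tidy(f1)$outer_fold, tidy(f3)$outer_fold))
})

test_that("pure-noise targets drive the penalty toward the heavy end of the grid", {
  set.seed(33)
  picks <- replicate(20, {
    X <- matrix(rnorm(60 * 30), 60, 30)
    fit_nested_cv(X, rnorm(60), seed = sample.int(1e6, 1))$selected_alpha
  })
  grid <- default_alpha_grid()
  expect_gt(sum(picks >= grid[10]), sum(picks <= grid[4]))
})

test_that("degenerate targets are rejected", {
  X <- matrix(rnorm(50 * 5), 50, 5)
  expect_error(fit_nested_cv(X, rep(1, 50)), "constant")
  expect_error(fit_nested_cv(X[1:8, ], rnorm(8)), "outer folds")
})

test_that("refit-and-evaluate reproduces a noiseless signal on a copy and rejects overlap", {
  set.seed(41)
  d <- make_linear_dataset(100, 8, k = 3, noise = 0)
  fit <- fit_nested_cv(d$X, d$y, seed = 2)
  same <- refit_and_evaluate(d$X, d$y, fit, d$X, d$y)
  expect_gt(same$r_rep, 0.999)

  Xn <- d$X
  colnames(Xn) <- paste0("e", 1:8)
  ft <- dplyr::bind_cols(
    tibble::tibble(subject_id = as.character(1:100)),
    tibble::as_tibble(Xn)
  )
  expect_error(
    refit_and_evaluate(ft[1:60, ], d$y[1:60], fit, ft[50:100, ], d$y[50:100]),
    "overlap"
  )
})

test_that("replication p-values are null-calibrated under permuted targets", {
  set.seed(51)
  ps <- replicate(100, {
    d <- make_linear_dataset(60, 10, noise = 1)
    y_perm <- sample(d$y)
    re <- refit_and_evaluate(
      d$X[1:30, ], d$y[1:30], 1,
      d$X[31:60, ], y_perm[31:60]
    )
    re$p_rep
  })
  # one-sided p under the null is Uniform(0,1)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("outer-ensemble-mean strategy is available and close to the refit", {
  set.seed(61)
  d <- make_linear_dataset(120, 10, k = 4, noise = 0.5)
  fit <- fit_nested_cv(d$X[1:60, ], d$y[1:60], seed = 3, keep_models = TRUE)
  r1 <- refit_and_evaluate(d$X[1:60, ], d$y[1:60], fit, d$X[61:120, ], d$y[61:120])
  r2 <- refit_and_evaluate(d$X[1:60, ], d$y[1:60], fit, d$X[61:120, ], d$y[61:120],
    strategy = "outer-ensemble-mean"
  )
  expect_gt(r1$r_rep, 0.8)
  expect_gt(r2$r_rep, 0.8)
  expect_error(
    refit_and_evaluate(d$X[1:60, ], d$y[1:60], 1, d$X[61:120, ], d$y[61:120],
      strategy = "outer-ensemble-mean"
    ),
    "keep_models"
  )
})

test_that("nested-CV discovery estimates are not optimistic relative to the oracle", {
  # over repeated draws, the mean discovery correlation must not exceed the
  # population correlation of the data-generating signal
  oracle <- sqrt(0.1)
  r_dis <- vapply(1:20, function(s) {
    set.seed(s + 900)
    n <- 200
    p <- 50
    X <- matrix(rnorm(n * p), n, p)
    w <- rnorm(5)
    signal <- as.numeric(X[, 1:5] %*% w) / sqrt(sum(w^2))
    y <- oracle * signal + sqrt(1 - oracle^2) * rnorm(n)
    fit_nested_cv(X, y, seed = s)$r_dis
  }, numeric(1))
  se <- sd(r_dis) / sqrt(length(r_dis))
  expect_lt(mean(r_dis), oracle + 2 * se)
})
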