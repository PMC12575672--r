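# Ridge regression solved in closed form via SVD.
#
# The whole resampling design refits ridge models tens of thousands of times
# on the same penalty grid, so the solver factorizes the (z-scored) training
# matrix once and evaluates every penalty from the same factorization:
# with X = U D V', coef(lambda) = V diag(d / (d^2 + lambda)) U' y.
# Features are standardized with training statistics only; the target is
# centered on the training mean (classic ridge with an unpenalized intercept).

ridge_path <- function(X, y, lambdas) {
  stopifnot(nrow(X) == length(y))
  mu <- colMeans(X)
  sdev <- sqrt(pmax(colMeans(X^2) - mu^2, 0) * nrow(X) / max(nrow(X) - 1, 1))
  sdev[sdev == 0] <- 1 # constant columns contribute nothing after centering
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  ybar <- mean(y)
  yc <- y - ybar

  k <- min(dim(Xs))
  sv <- svd(Xs, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  uty <- crossprod(sv$u, yc) # k x 1
  # k x L matrix of shrunken spectral coefficients, one column per penalty
  shrink <- outer(as.numeric(uty) * d, rep(1, length(lambdas))) /
    outer(d^2, lambdas, "+")
  beta <- sv$v %*% shrink # p x L, on the standardized scale

  structure(
    list(
      beta = beta, lambdas = lambdas,
      center = mu, scale = sdev, intercept = ybar
    ),
    class = "ridge_path"
  )
}

# Predictions for all penalties at once: n x L matrix.
predict_ridge_path <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
  Xs %*% fit$beta + fit$intercept
}

# Coefficients for one penalty on the original feature scale.
ridge_coefficients <- function(fit, lambda) {
  j <- which(fit$lambdas == lambda)[1]
  if (is.na(j)) abort("lambda not on the fitted path")
  b <- fit$beta[, j] / fit$scale
  list(coefficients = b, intercept = fit$intercept - sum(b * fit$center))
}
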