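# Small fixtures built in code; no data files.

# Bivariate-normal pair with population correlation rho.
make_gaussian_pair <- function(n, rho) {
  z <- matrix(rnorm(2 * n), n, 2)
  list(x = z[, 1], y = rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
}

# Dense feature matrix with y exactly linear in the first k features plus
# optional noise.
make_linear_dataset <- function(n, p, k = 5, noise = 0) {
  X <- matrix(rnorm(n * p), n, p)
  w <- rnorm(k)
  y <- as.numeric(X[, seq_len(k)] %*% w) + rnorm(n, sd = noise)
  list(X = X, y = y, w = w)
}

# Shuffle-record table with prescribed significance pattern.
make_records <- function(n_dis_sig, n_both_sig, n_total, n = 100) {
  stopifnot(n_both_sig <= n_dis_sig, n_dis_sig <= n_total)
  p_dis <- c(rep(0.01, n_dis_sig), rep(0.5, n_total - n_dis_sig))
  p_rep <- c(
    rep(0.01, n_both_sig), rep(0.5, n_dis_sig - n_both_sig),
    rep(0.01, n_total - n_dis_sig) # rep significance without dis must not count
  )
  tibble::tibble(
    n = n, shuffle = seq_len(n_total), p_dis = p_dis, p_rep = p_rep,
    r_dis = ifelse(p_dis < 0.05, 0.3, 0.02),
    r_rep = ifelse(p_rep < 0.05, 0.3, 0.02)
  )
}

# Random symmetric matrix with zero diagonal.
make_symmetric <- function(n) {
  m <- matrix(rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
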