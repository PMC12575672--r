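# Effect-size-driven theoretical replication probability.
#
# Given an observed prediction-observation correlation r at sample size n,
# the t statistic of a future same-size replication attempt is predicted by a
# K-prime distribution: a noncentral-t variate whose noncentrality is itself
# scaled by an independent chi factor, reflecting that both the effect and
# the error variance were only estimated. The probability that this
# predictive t exceeds the critical value at level alpha is the probability
# of significant replication, and inverting it in n yields the theoretical
# sample size required for a target replication probability.

#' t statistic of a Pearson correlation
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))`, the usual t transform of a sample
#' correlation with `n - 2` degrees of freedom.
#'
#' @param r Correlation, `|r| < 1`.
#' @param n Sample size, `n >= 3`.
#' @return The t value (vectorized over `r` and `n`).
#' @examples
#' t_from_r(0.5, 27)
#' @export
t_from_r <- function(r, n) {
  if (any(abs(r) >= 1)) abort("|r| must be < 1")
  if (any(n < 3)) abort("n must be >= 3")
  r * sqrt((n - 2) / (1 - r^2))
}

# Density of chi_v / sqrt(v) (the scaling factor of the K-prime
# noncentrality), evaluated on the log scale for stability at large v.
dchi_scaled <- function(s, v) {
  out <- numeric(length(s))
  pos <- s > 0
  lg <- (v / 2) * log(v) - (v / 2 - 1) * log(2) - lgamma(v / 2) +
    (v - 1) * log(s[pos]) - v * s[pos]^2 / 2
  out[pos] <- exp(lg)
  out
}

#' Survival function of the K-prime distribution
#'
#' `K'_{v1,v2}(ncp)` is the distribution of a noncentral-t variate with `v2`
#' degrees of freedom whose noncentrality parameter is `ncp` multiplied by an
#' independent `chi_{v1} / sqrt(v1)` factor. It arises as the predictive
#' distribution of a future t statistic when both the effect size and the
#' error variance behind the observed t are uncertain.
#'
#' The default evaluation integrates the noncentral-t survival function over
#' the chi density (deterministic quadrature); `"montecarlo"` draws the
#' two-stage variate directly and is retained as an independent check.
#'
#' @param q Quantile.
#' @param v1 Degrees of freedom of the chi scaling factor (>= 1).
#' @param v2 Degrees of freedom of the t variate (>= 1).
#' @param ncp Noncentrality before chi scaling.
#' @param method `"quadrature"` (default) or `"montecarlo"`.
#' @param mc_draws Monte Carlo sample size (default 2e5).
#' @param seed Seed for the Monte Carlo method.
#' @return `Pr(K' > q)`.
#' @examples
#' kprime_survival(0, 10, 10, 0) # central t: exactly 0.5
#' @export
kprime_survival <- function(q, v1, v2, ncp,
                            method = c("quadrature", "montecarlo"),
                            mc_draws = 2e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(v1 >= 1, v2 >= 1)
  if (!is.finite(q)) {
    if (is.na(q)) abort("q must not be NA")
    return(if (q < 0) 1 else 0)
  }
  if (!is.finite(ncp)) abort("ncp must be finite")
  if (ncp == 0) {
    # chi factor multiplies zero: reduces exactly to central t with v2 df
    return(pt(q, df = v2, lower.tail = FALSE))
  }
  if (method == "quadrature") {
    f <- function(s) dchi_scaled(s, v1) * pt(q, df = v2, ncp = ncp * s, lower.tail = FALSE)
    # the chi/sqrt(v1) factor concentrates around 1 with sd ~ 1/sqrt(2 v1)
    upper <- max(10, 1 + 20 / sqrt(v1))
    integrate(f, 0, upper, rel.tol = 1e-8, abs.tol = 1e-10)$value
  } else {
    with_local_seed(seed, {
      s <- sqrt(rchisq(mc_draws, v1) / v1)
      num <- rnorm(mc_draws) + ncp * s
      den <- sqrt(rchisq(mc_draws, v2) / v2)
      mean(num / den > q)
    })
  }
}

#' Probability of significant replication from an observed effect size
#'
#' For an observed correlation `r` at sample size `n`, the probability that
#' an independent same-size replication attempt reaches significance at level
#' `alpha`: `Pr(t_rep > T_alpha | t_obs) =
#' Pr(K'_{(v,v)}(t_obs / sqrt(2)) > T_alpha / sqrt(2))` with `v = n - 2`,
#' `t_obs = t_from_r(r, n)` and `T_alpha` the critical t value. The
#' `sqrt(2)` scaling reflects that discovery and replication samples are the
#' same size, so the predictive uncertainty of the replication t doubles.
#'
#' Sidedness of the critical value defaults to two-sided, the calibration
#' under which the solver reproduces the package's reference worked examples;
#' see the methods vignette.
#'
#' @param r Observed correlation, `|r| < 1`.
#' @param n Sample size (>= 4).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param sided `"two"` (default) or `"one"` critical value.
#' @param method Passed to [kprime_survival()].
#' @return Probability of significant replication.
#' @examples
#' p_srep(0.19, 269)
#' @export
p_srep <- function(r, n, alpha = 0.05, sided = c("two", "one"),
                   method = c("quadrature", "montecarlo")) {
  sided <- match.arg(sided)
  method <- match.arg(method)
  if (abs(r) >= 1) abort("|r| must be < 1")
  if (n < 4) abort("degenerate degrees of freedom: need n >= 4")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  v <- n - 2
  t_obs <- t_from_r(r, n)
  t_alpha <- if (sided == "one") qt(1 - alpha, v) else qt(1 - alpha / 2, v)
  kprime_survival(t_alpha / sqrt(2), v, v, t_obs / sqrt(2), method = method)
}

#' Theoretical sample size for a target replication probability
#'
#' The smallest integer `n` (up to `n_max`) at which [p_srep()] reaches
#' `target_prob`. Because the replication probability is monotonically
#' increasing in `n` for fixed positive `r`, the solver bisects on `n` (step
#' 1, not any empirical grid step). Returns the sentinel `NA` when the target
#' is not reached by `n_max` — in particular for `r = 0`, which never
#' replicates above chance.
#'
#' @param r Observed correlation.
#' @param alpha Significance level (default 0.05).
#' @param target_prob Required replication probability (default 0.8).
#' @param n_max Search bound (default 1000).
#' @param sided Passed to [p_srep()].
#' @return An object of class `theoretical_estimate` (one-row tibble with
#'   `r`, `alpha`, `target_prob`, `n_T`, `p_srep_at_n`).
#' @examples
#' theoretical_n(0.32)
#' @export
theoretical_n <- function(r, alpha = 0.05, target_prob = 0.8, n_max = 1000,
                          sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (target_prob <= 0 || target_prob >= 1) abort("target_prob must be in (0, 1)")
  ps <- function(n) p_srep(r, n, alpha = alpha, sided = sided)
  n_T <- NA_integer_
  p_at <- NA_real_
  if (r > 0 && ps(n_max) >= target_prob) {
    lo <- 4L
    hi <- as.integer(n_max)
    if (ps(lo) >= target_prob) {
      hi <- lo
    } else {
      while (hi - lo > 1L) {
        mid <- (lo + hi) %/% 2L
        if (ps(mid) >= target_prob) hi <- mid else lo <- mid
      }
    }
    n_T <- hi
    p_at <- ps(hi)
  }
  out <- tibble::tibble(
    r = r, alpha = alpha, target_prob = target_prob,
    n_T = n_T, p_srep_at_n = p_at, n_max = n_max, sided = sided
  )
  class(out) <- c("theoretical_estimate", class(out))
  out
}

#' @export
print.theoretical_estimate <- function(x, ...) {
  if (is.na(x$n_T)) {
    cat(sprintf(
      "<theoretical_estimate> r = %g: target P_srep = %g not reached by n = %d\n",
      x$r, x$target_prob, x$n_max
    ))
  } else {
    cat(sprintf(
      "<theoretical_estimate> r = %g: n_T = %d (P_srep = %.3f >= %g at alpha = %g, %s-sided)\n",
      x$r, x$n_T, x$p_srep_at_n, x$target_prob, x$alpha, x$sided
    ))
  }
  invisible(x)
}

#' Compare empirical and theoretical minimum sample sizes
#'
#' Pearson correlation between empirically estimated minimum replicable
#' sample sizes (`n_E`, from the split-resample engine) and effect-size-driven
#' theoretical sample sizes (`n_T`), across phenotypes. Pairs with a sentinel
#' (`NA`) on either side are excluded.
#'
#' @param pairs Data frame with columns `n_E` and `n_T` (other columns, e.g.
#'   `phenotype`, are carried through).
#' @return A list with `correlation`, `n_pairs` (finite pairs used) and
#'   `table` (the input restricted to finite pairs).
#' @examples
#' compare_empirical_theoretical(
#'   tibble::tibble(n_E = c(50, 150, 300), n_T = c(65, 140, 310))
#' )
#' @export
compare_empirical_theoretical <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("n_E", "n_T") %in% names(pairs)))
  ok <- is.finite(pairs$n_E) & is.finite(pairs$n_T)
  if (sum(ok) < 3) {
    abort("insufficient data: need at least 3 phenotypes with finite n_E and n_T")
  }
  tab <- pairs[ok, , drop = FALSE]
  list(
    correlation = cor(tab$n_E, tab$n_T),
    n_pairs = nrow(tab),
    table = tibble::as_tibble(tab)
  )
}
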