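---
title: "Assessing the replicability of connectome-based predictive models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the replicability of connectome-based predictive models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Brain-wide association studies (BWAS) relate inter-individual differences in
brain measures — here, structural-connectome edge weights derived from
diffusion MRI — to behavioral phenotypes. Multivariate predictive models
(one phenotype regressed on thousands of edges) achieve larger effect sizes
than mass-univariate maps, but their replicability at realistic sample sizes
is an empirical question: how often does a model that looks significant in a
discovery cohort reach significance again in an independent, same-size
replication cohort? `repliconn` implements the two complementary answers —
a resampling engine that measures replication probability directly, and a
closed-form predictive model of the replication t statistic — together with
a synthetic connectome generator that makes the entire pipeline testable
against planted ground truth.

# The empirical engine

## Split design

For a cohort of N subjects and a per-half sample size n, each *shuffle*
draws two disjoint subject sets of size n uniformly at random without
replacement (`draw_split()`): a discovery half used to train and tune the
model, and a replication half used once, for independent evaluation. No
demographic matching or stratification is applied — the replication half is
deliberately an arbitrary unseen sample from the same population, which is
the form of generalization the analysis is meant to probe.

## Model stage

On the discovery half, ridge regression is fit under nested
cross-validation (`fit_nested_cv()`): a 5-fold outer loop yields one
out-of-fold prediction per subject, while a 5-fold inner loop inside each
outer training partition selects the ridge penalty from a fixed grid of 13
log-spaced values, $10^{-3}$ to $10^{5}$. The grid is wide by design: its
heavy end shrinks coefficients essentially to zero, so "no predictable
signal" is always expressible. Features are z-scored with training-partition
statistics only; the target is centered on the training mean (classic ridge
with an unpenalized intercept). The solver factorizes each training matrix
once by SVD and evaluates the whole penalty path from that factorization.

The discovery effect size is
$r_{dis} = \mathrm{cor}(y, \hat y_{oof})$ over the pooled out-of-fold
predictions, with a t-based p-value (`corr_pvalue()`), one-sided toward
positive association by default: only a positive prediction–observation
correlation indicates predictive skill. The replication stage
(`refit_and_evaluate()`) refits one model on the full discovery half at a
penalty re-selected on it, applies it to the replication half, and computes
$r_{rep}$ and $p_{rep}$ the same way. An ensemble alternative (mean of the
outer-loop models' predictions) is available as a config switch.

Three numerical choices deserve emphasis:

* **Inner-loop score.** The inner loop selects the penalty by held-out
  predictive $R^2$ ($1 - SSE/SST$), not by held-out correlation.
  Correlation is scale-invariant, so a near-zero penalty that interpolates
  the training fold — producing predictions with wildly inflated variance —
  can tie with a well-shrunk fit. When one outer fold picks such a penalty,
  its predictions dominate the variance of the pooled out-of-fold vector and
  wreck $r_{dis}$ even when other folds behave. Predictive $R^2$ penalizes
  the scale error and selects sanely; it is also the default regression
  scorer of the mainstream ML toolchain, so curves computed here are
  comparable to common practice. Correlation scoring remains available
  (`inner_score = "cor"`).
* **Pooling.** Each outer fold's model carries its own intercept — the
  training-partition mean, which is anti-correlated with the held-out
  fold's mean — so pooling raw predictions biases the discovery correlation
  negative (down to roughly −0.25 at n = 25 on null targets) and destroys
  the null calibration of $p_{dis}$. By default each fold's predictions are
  therefore *centered* before pooling (`pooling = "fold-centered"`), which
  removes the intercept bias while leaving each fold's output scale — its
  share of the pooled variance — untouched. Full per-fold standardization
  is deliberately not the default: it over-weights weakly fitting folds,
  and because fold estimates are positively dependent it inflates the null
  variance of the pooled correlation (measured type-I error 0.13 instead of
  0.05). Under fold-centering the permutation-measured type-I error of the
  one-sided discovery test sits at the nominal level across the dimensions
  the tests probe.
* **Tie-break.** Exact score ties resolve toward the larger penalty (more
  regularization), making selection deterministic.

## Aggregation

For each sample size, the replication probability is the conditional
fraction

$$P_{replicability} = \frac{\#\{p_{rep} < \alpha \wedge p_{dis} < \alpha\}}
                           {\#\{p_{dis} < \alpha\}}$$

over shuffles (`estimate_p_replicability()`). When the denominator is zero
the probability is *undefined* and reported as `NA`, never 0 — "the effect
was never discovered" and "the effect does not replicate" are different
findings, and conflating them would misrank weak phenotypes. Denominators
below 10 are flagged as low-confidence. The minimum replicable sample size
$n_E$ (`min_replicable_n()`) is the first grid point whose probability
strictly exceeds the threshold (default 0.8); undefined entries fail the
comparison. A phenotype measured with several connectome weightings (SC,
FA, RD, AD, ADC) counts as replicable under the union rule when at least
one weighting replicates (`union_replicability()`).

The default grid runs from 25 to 425 in steps of 25. Sample sizes beyond
half the cohort are truncated with a warning rather than an error, so a
config written for a larger cohort degrades gracefully.

Every (phenotype, metric, sample size, shuffle) cell derives its own seed
from the master seed (`derive_seed()`, a Lehmer-style integer mix), so any
cell can be recomputed in isolation, records are exchangeable, and
aggregation is order-free. With a `record_file`, records append as they are
produced and interrupted runs resume from disk.

# The theoretical engine

The engine above is expensive; the theory module answers the planning
question — *what sample size would this effect size need?* — in closed
form. For an observed correlation $r$ at sample size $n$, the t statistic
is $t_{obs} = r\sqrt{(n-2)/(1-r^2)}$ with $v = n-2$ degrees of freedom. The
t statistic of a future same-size replication is predicted by a K-prime
distribution: a noncentral-t variate with $v$ degrees of freedom whose
noncentrality is itself scaled by an independent $\chi_v/\sqrt{v}$ factor,
reflecting that both the effect and the error variance behind $t_{obs}$
were estimated rather than known. The probability of significant
replication at level $\alpha$ is

$$P_{srep}(\alpha) = \Pr(t_{rep} > T_\alpha \mid t_{obs})
 = \Pr\!\left[K'_{(v,v)}\!\left(t_{obs}/\sqrt{2}\right) > T_\alpha/\sqrt{2}\right],$$

where $T_\alpha$ is the critical t value and the $\sqrt 2$ scaling encodes
the doubling of predictive uncertainty when discovery and replication
samples are the same size. `kprime_survival()` evaluates the survival
function by deterministic quadrature (integrating the noncentral-t survival
over the chi density, relative tolerance $10^{-8}$); a seeded Monte Carlo
evaluation of the same two-stage variate is retained purely as an
independent cross-check, and the test suite verifies the two agree within
Monte-Carlo error across a grid of effect sizes and sample sizes. At zero
noncentrality the distribution collapses exactly to a central t, which the
implementation special-cases and the tests pin down.

`theoretical_n()` inverts $P_{srep}$ in $n$: since the probability is
monotonically increasing in $n$ for fixed positive $r$, a bisection at step
1 (not any empirical grid step) finds the smallest $n \le n_{max}$
(default 1000) reaching the target probability (default 0.8). For $r \le 0$
or targets unreachable by $n_{max}$ it returns a sentinel `NA`.

**Sidedness.** The formula leaves the sidedness of $T_\alpha$ open. The
package defaults to the two-sided critical value, matching the convention
that replication success is declared at two-sided $p < .05$; under this
calibration the solver's worked examples land within one sample of the
reference values for $r = 0.19$ and $r = 0.32$ (270 and 92). No sidedness
reproduces all three commonly quoted reference sizes for
$r = 0.14/0.19/0.32$ simultaneously — at $r = 0.14$ the two-sided solver
requires 502 — and the package reports what its own formulas compute rather
than forcing agreement. Both conventions are exposed (`sided`), and the
choice is recorded in the experiment manifest. Note the asymmetry with the
empirical engine's default *one-sided* model p-values: the engine tests
directional predictive skill, while the theory module predicts conventional
two-sided significance; both defaults can be overridden per run.

`compare_empirical_theoretical()` closes the loop: across phenotypes, the
empirical $n_E$ is paired with the theoretical $n_T$ computed from the mean
replication-half effect size at $n_E$ (replication-half, because discovery
estimates are selected for significance at $n_E$ and therefore optimistic),
and their Pearson correlation measures how well effect size alone explains
replicability.

# The synthetic cohort generator

Access-restricted cohort data cannot ship with a package, so every
downstream stage is validated against synthetic cohorts with known ground
truth (`synth_config()`, `generate_features()`, `generate_phenotype()`).
The generator emulates the *statistical shape* of a structural-connectome
study, not any real cohort's marginals:

* **Features.** An atlas of `n_nodes` regions (default 84, giving
  $84\cdot83/2 = 3486$ unique edges) with either `sparse-lognormal` edges —
  present with probability 0.6, lognormal weight when present: nonnegative,
  right-skewed, with structural zeros, like streamline counts — or
  `dense-gaussian` standardized edges, like tract-averaged diffusivity
  features. Sparse-lognormal is the default, as streamline-based
  connectomes are the primary use case.
* **Signal.** `n_informative` edges (default one tenth of the edge count)
  receive i.i.d. Gaussian weights, rescaled so the planted linear signal
  has unit population variance (edge variances are known analytically under
  both feature models). The phenotype is
  $y = \sqrt{\rho^2_{true}\cdot rel}\; s + w_c\, c + \sqrt{1 - \rho^2_{true}\cdot rel}\;\varepsilon$,
  so the population correlation of the oracle predictor $Xw_{true}$ with
  $y$ is exactly $\sqrt{\rho^2_{true}\cdot rel}$ when $w_c = 0$. The test
  suite verifies this calibration to within ±0.01 over 50 seeds at
  n = 2000.
* **Reliability.** Test-retest reliability enters as pure attenuation —
  extra phenotype noise multiplying the signal variance — which is how
  trait versus state stability caps achievable effect sizes; no
  longitudinal structure is invented.
* **Confounder.** A positive lognormal scalar per subject (TIV-like, ~20%
  coefficient of variation) optionally enters both a random 30% of edges
  and the phenotype. This is the minimal structure needed to exercise
  confounder-leakage checks; with a nonzero weight the oracle calibration
  above is only approximate, which is documented rather than corrected.

Everything is deterministic in the config seed, with independent sub-seeds
per draw (confounder, features, signal placement, noise).

What passing tests on this generator do **not** show: real connectomes have
correlated edges, site and acquisition effects, non-Gaussian phenotype
distributions and missingness; none of these are modeled. Conclusions about
the pipeline's statistical behavior (calibration, monotonicity,
empirical-theoretical agreement) transfer; absolute effect sizes and sample
sizes do not.

# Validation-scale choices

The package's own end-to-end validation (`demo_experiment_config()`) uses a
900-subject cohort with a 25-node atlas (300 edges), six trait-like
phenotypes with true predictable variance 1, 2, 4, 8, 16 and 25%, 20
shuffles per sample size and the grid 25–425 in steps of 50. These sizes
keep a full run in the minutes range on a single core while preserving the
phenomena of interest: null and near-null phenotypes stay unreplicable,
strong ones saturate early, and empirical $n_E$ tracks theoretical $n_T$.
With 20 shuffles the replication-probability estimates are coarse
(granularity 1/20 at full denominator) and $n_E$ for borderline phenotypes
is accordingly noisy; the low-confidence flag marks sample sizes whose
denominators are below 10, and such crossings do not set $n_E$.

At these dimensions it is worth noting what a "strong" phenotype can
achieve: with 300 *independent* features, n = 425 training subjects and
25% true predictable variance (oracle r = 0.5), the best possible ridge
fit reaches an out-of-sample correlation of only about 0.2–0.3, and this
ceiling varies considerably across generator seeds under the heavy-tailed
edge model — high-dimensional estimation loss, not a defect. Discovery
estimates additionally pay the nested-CV price (models trained on 4/5 of
the half, pooled across folds), which is why discovery effect sizes sit
below replication effect sizes at small n, converging as n grows — the
delta-r sign pattern the tests assert. Real connectomes behave better than
this worst case: their edges are strongly correlated, so the effective
dimensionality is far below the edge count and multivariate models recover
a much larger share of the true effect. One practical consequence at the
demo scale is that only the strongest synthetic phenotypes attain a
*confident* minimum replicable sample size within the grid; when fewer
than three phenotypes do, the empirical-theoretical correlation over
phenotypes is reported as undefined rather than computed from a degenerate
pair count.

# Degenerate inputs and edge cases

* Constant targets are rejected before fitting; constant pooled predictions
  yield an undefined correlation and p = 1 by convention.
* `p_srep()` requires n ≥ 4 (positive degrees of freedom); `t_from_r()`
  requires |r| < 1.
* Outlier filtering (`filter_outliers()`, k = 3 standard deviations,
  computed once on the full target vector) is off by default — the primary
  analysis convention — and is never applied inside cross-validation folds.
* Subjects missing a phenotype value are dropped per-target at join time,
  with a message.
* Grid points requiring more subjects than available are truncated with a
  warning; an entirely infeasible grid is an error.

# Known limitations

* The engine treats shuffles as exchangeable and aggregates order-free, but
  shuffles at different sample sizes share subjects and are therefore not
  independent; Monte-Carlo error formulas for $P_{replicability}$ are
  approximate.
* The K-prime machinery predicts replication of the *univariate*
  prediction-observation correlation; it does not model penalty
  re-selection or feature-set instability across replications.
* Binary phenotypes are treated as 0/1 regression targets scored by
  Pearson correlation, consistent with the engine's single effect-size
  currency, not as a classification problem.
* With few shuffles, the conditional definition of $P_{replicability}$ can
  cross the threshold on a denominator of one or two; inspect the
  low-confidence flags (or raise `n_shuffles`) before trusting a borderline
  $n_E$.
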