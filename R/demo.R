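# A validation-scale demo experiment used by the examples, the reproduction
# script and the test-suite's end-to-end checks.

#' Config for the scaled-down six-phenotype demo experiment
#'
#' A complete experiment config at desk scale: a 900-subject synthetic cohort
#' with 300 edge features (a 25-node atlas) and six trait-like phenotypes
#' whose true predictable variance spans 1% to 25% — the effect-size range
#' from "barely there" to "strong multivariate signature". The engine runs 20
#' shuffles per sample size on the grid 25 to 425 in steps of 50. At this
#' scale the full experiment takes a few minutes on one CPU and reproduces
#' the qualitative structure of the full-size analysis: weak phenotypes never
#' replicate within the grid, strong ones replicate early, and the empirical
#' minimum sample sizes track the effect-size-driven theoretical ones.
#'
#' @param seed Master seed for the whole experiment.
#' @return A config list for [run_experiment()].
#' @examples
#' cfg <- demo_experiment_config(seed = 1)
#' names(cfg)
#' @export
demo_experiment_config <- function(seed = 1) {
  r2s <- c(0.01, 0.02, 0.04, 0.08, 0.16, 0.25)
  list(
    seed = seed,
    grid = list(from = 25, to = 425, by = 50),
    n_shuffles = 20,
    alpha = 0.05,
    threshold = 0.8,
    metrics = "SC",
    synthetic = list(
      n_subjects = 900,
      n_nodes = 25, # 300 unique edges
      feature_model = "sparse-lognormal",
      reliability = 1,
      confound_weight = 0,
      phenotypes = lapply(r2s, function(r2) {
        list(
          name = sprintf("pheno_r2_%02d", round(100 * r2)),
          true_r2 = r2, category = "trait"
        )
      })
    )
  )
}
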