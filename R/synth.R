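# Synthetic connectome features and phenotypes with planted effects.
#
# The generator stands in for restricted cohort data: it emulates the
# *statistical shape* of a structural-connectome study (an 84-node atlas gives
# 3486 unique edges; streamline-count edges are sparse, nonnegative and
# right-skewed) while planting a linear effect of known population magnitude,
# so every downstream estimate can be checked against ground truth. It makes
# no attempt to reproduce the marginal distributions of any real cohort.

#' Configuration for the synthetic connectome generator
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_nodes Number of atlas nodes (>= 2); features are the
#'   `n_nodes * (n_nodes - 1) / 2` unique edges. Default 84, the resolution of
#'   the Desikan-Killiany atlas commonly used for structural connectomes.
#' @param true_r2 Fraction in `[0, 1)`: population variance of the phenotype
#'   explained by the optimal linear readout of the features.
#' @param reliability Fraction in `(0, 1]`: test-retest attenuation multiplying
#'   the signal variance. Trait-like phenotypes have high reliability,
#'   state-like ones low; the oracle correlation is
#'   `sqrt(true_r2 * reliability)`.
#' @param confound_weight Nonnegative strength of a TIV-like positive scalar
#'   confounder that enters both a subset of features and the phenotype.
#'   Default 0 (no confounding); with a nonzero weight the oracle calibration
#'   is only approximate.
#' @param feature_model `"sparse-lognormal"` (streamline-count-like:
#'   nonnegative, right-skewed, with structural zeros) or `"dense-gaussian"`
#'   (standardized, FA-like). Default sparse-lognormal.
#' @param n_informative Number of edges carrying signal; default one tenth of
#'   the edge count (rounded up).
#' @param seed Integer seed; the full generator path is deterministic in it.
#' @return A `synth_config` list.
#' @examples
#' cfg <- synth_config(n_subjects = 100, n_nodes = 10, true_r2 = 0.1, seed = 1)
#' @export
synth_config <- function(n_subjects,
                         n_nodes = 84,
                         true_r2 = 0.1,
                         reliability = 1,
                         confound_weight = 0,
                         feature_model = c("sparse-lognormal", "dense-gaussian"),
                         n_informative = NULL,
                         seed = 1) {
  feature_model <- match.arg(feature_model)
  if (n_subjects < 2 || n_nodes < 2) {
    abort("invalid config: n_subjects and n_nodes must both be >= 2")
  }
  if (true_r2 < 0 || true_r2 >= 1) abort("true_r2 must be in [0, 1)")
  if (reliability <= 0 || reliability > 1) abort("reliability must be in (0, 1]")
  if (true_r2 * reliability >= 1) abort("true_r2 * reliability must be < 1")
  if (confound_weight < 0) abort("confound_weight must be nonnegative")
  n_edges <- n_nodes * (n_nodes - 1) / 2
  n_informative <- n_informative %||% ceiling(n_edges / 10)
  if (n_informative < 1 || n_informative > n_edges) {
    abort(sprintf("n_informative must be in [1, %d]", n_edges))
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
      n_edges = as.integer(n_edges), true_r2 = true_r2,
      reliability = reliability, confound_weight = confound_weight,
      feature_model = feature_model, n_informative = as.integer(n_informative),
      seed = as.integer(seed),
      # sparse-lognormal shape parameters (edge present w.p. density; positive
      # weights lognormal(meanlog, sdlog) when present)
      density = 0.6, meanlog = 0, sdlog = 1,
      # TIV-like confounder: lognormal with ~20% coefficient of variation
      confound_sdlog = 0.2, confound_frac_edges = 0.3
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d subjects, %d nodes (%d edges), %s features\n",
    x$n_subjects, x$n_nodes, x$n_edges, x$feature_model
  ))
  cat(sprintf(
    "  true_r2 = %g, reliability = %g (oracle r = %.3f), confound_weight = %g, seed = %d\n",
    x$true_r2, x$reliability, sqrt(x$true_r2 * x$reliability),
    x$confound_weight, x$seed
  ))
  invisible(x)
}

# Population variance of a single edge under the configured feature model.
edge_variance <- function(config) {
  switch(config$feature_model,
    "dense-gaussian" = 1,
    "sparse-lognormal" = {
      q <- config$density
      m2 <- exp(2 * config$meanlog + 2 * config$sdlog^2)
      m1 <- exp(config$meanlog + config$sdlog^2 / 2)
      q * m2 - (q * m1)^2
    }
  )
}

edge_label_grid <- function(n_nodes) {
  labels <- sprintf("n%03d", seq_len(n_nodes))
  ij <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  paste(labels[ij[, "row"]], labels[ij[, "col"]], sep = "-")
}

#' Generate a synthetic connectome feature table
#'
#' Draws `n_subjects` rows of `n_nodes * (n_nodes - 1) / 2` edge features under
#' the configured model. The subject-level confounder is drawn here (so that
#' features and phenotype see the same realization) and attached to the result,
#' together with the config, as attribute `synth_meta`.
#'
#' @param config A [synth_config()].
#' @return A tibble with `subject_id` and one column per edge, labelled
#'   `"nodeA-nodeB"`. Attribute `synth_meta` carries the config, the confounder
#'   vector and the indices of confound-contaminated edges.
#' @examples
#' f <- generate_features(synth_config(20, n_nodes = 5, seed = 7))
#' dim(f)
#' @export
generate_features <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_subjects
  e <- config$n_edges
  confounder <- with_local_seed(
    derive_seed(config$seed, 1),
    rlnorm(n, meanlog = 0, sdlog = config$confound_sdlog)
  )
  X <- with_local_seed(derive_seed(config$seed, 2), {
    if (config$feature_model == "dense-gaussian") {
      matrix(rnorm(n * e), n, e)
    } else {
      present <- matrix(rbinom(n * e, 1, config$density), n, e)
      present * matrix(rlnorm(n * e, config$meanlog, config$sdlog), n, e)
    }
  })
  confounded_edges <- integer(0)
  if (config$confound_weight > 0) {
    confounded_edges <- with_local_seed(
      derive_seed(config$seed, 3),
      sort(sample.int(e, size = max(1, round(config$confound_frac_edges * e))))
    )
    X[, confounded_edges] <- X[, confounded_edges] +
      config$confound_weight * confounder
  }
  colnames(X) <- edge_label_grid(config$n_nodes)
  out <- tibble::tibble(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    tibble::as_tibble(X)
  )
  attr(out, "synth_meta") <- list(
    config = config, confounder = confounder,
    confounded_edges = confounded_edges
  )
  out
}

#' Generate a phenotype with a planted, variance-calibrated effect
#'
#' Plants Gaussian weights on `n_informative` randomly chosen edges and builds
#' `y = sqrt(true_r2 * reliability) * s + confound_weight * c + noise`, where
#' `s` is the planted linear signal rescaled to unit population variance and
#' `c` the standardized confounder. With `confound_weight = 0` the population
#' correlation between the oracle predictor `X w_true` and `y` is exactly
#' `sqrt(true_r2 * reliability)`; reliability acts as pure attenuation (extra
#' phenotype noise), the way test-retest reliability caps the achievable
#' effect size of a trait or state measure.
#'
#' @param features Feature table produced by [generate_features()] under the
#'   same config.
#' @param config The same [synth_config()].
#' @return A list of class `synth_phenotype` with `phenotype` (tibble
#'   `subject_id`, `value`), `weights` (named numeric, zero off the informative
#'   set), `informative` (edge indices), `confounder` (tibble), `oracle_r`
#'   (the target population correlation), and `config`.
#' @examples
#' cfg <- synth_config(200, n_nodes = 8, true_r2 = 0.2, seed = 3)
#' ph <- generate_phenotype(generate_features(cfg), cfg)
#' cor(as.matrix(generate_features(cfg)[-1]) %*% ph$weights, ph$phenotype$value)
#' @export
generate_phenotype <- function(features, config) {
  stopifnot(inherits(config, "synth_config"))
  meta <- attr(features, "synth_meta")
  fm <- as_feature_matrix(features)
  if (nrow(fm$X) != config$n_subjects || ncol(fm$X) != config$n_edges) {
    abort(sprintf(
      "feature table (%d x %d) does not match config (%d x %d)",
      nrow(fm$X), ncol(fm$X), config$n_subjects, config$n_edges
    ))
  }
  if (is.null(meta)) {
    if (config$confound_weight > 0) {
      abort("features lack generator metadata; regenerate with generate_features()")
    }
    confounder <- rep(1, config$n_subjects)
  } else {
    confounder <- meta$confounder
  }

  e <- config$n_edges
  planted <- with_local_seed(derive_seed(config$seed, 4), {
    idx <- sort(sample.int(e, config$n_informative))
    w <- rnorm(config$n_informative)
    list(idx = idx, w = w)
  })
  # Rescale the planted weights so the population variance of the signal is 1
  # (edges are independent under both feature models, before confounding).
  w_full <- numeric(e)
  w_full[planted$idx] <- planted$w /
    sqrt(edge_variance(config) * sum(planted$w^2))
  names(w_full) <- colnames(fm$X)

  r2_eff <- config$true_r2 * config$reliability
  s <- as.numeric(fm$X %*% w_full)
  c_std <- if (sd(confounder) > 0) {
    (confounder - mean(confounder)) / sd(confounder)
  } else {
    rep(0, length(confounder))
  }
  noise <- with_local_seed(
    derive_seed(config$seed, 5),
    rnorm(config$n_subjects)
  )
  y <- sqrt(r2_eff) * (s - mean(s)) +
    config$confound_weight * c_std +
    sqrt(1 - r2_eff) * noise

  structure(
    list(
      phenotype = tibble::tibble(subject_id = fm$ids, value = y),
      weights = w_full,
      informative = planted$idx,
      confounder = tibble::tibble(subject_id = fm$ids, confounder = confounder),
      oracle_r = sqrt(r2_eff),
      config = config
    ),
    class = "synth_phenotype"
  )
}

#' @export
print.synth_phenotype <- function(x, ...) {
  cat(sprintf(
    "<synth_phenotype> %d subjects, %d informative edges, oracle r = %.3f\n",
    nrow(x$phenotype), length(x$informative), x$oracle_r
  ))
  invisible(x)
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' Writes `features.tsv`, `phenotype.tsv`, `truth_weights.tsv` (edge, weight)
#' and `meta.yaml` (config plus planted-truth summary) into `dir`, so a run
#' can be reloaded and audited without regenerating.
#'
#' @param features Output of [generate_features()].
#' @param phenotype Output of [generate_phenotype()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(features, phenotype, dir) {
  stopifnot(inherits(phenotype, "synth_phenotype"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(features, file.path(dir, "features.tsv"))
  write_phenotype_table(phenotype$phenotype, file.path(dir, "phenotype.tsv"))
  readr::write_tsv(
    tibble::tibble(edge = names(phenotype$weights), weight = phenotype$weights),
    file.path(dir, "truth_weights.tsv"), progress = FALSE
  )
  cfg <- phenotype$config
  yaml::write_yaml(
    list(
      config = unclass(cfg)[c(
        "n_subjects", "n_nodes", "n_edges", "true_r2", "reliability",
        "confound_weight", "feature_model", "n_informative", "seed"
      )],
      oracle_r = phenotype$oracle_r,
      informative_edges = phenotype$informative
    ),
    file.path(dir, "meta.yaml")
  )
  invisible(dir)
}
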