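# End-to-end experiment driver: synthetic cohort -> replication curves ->
# empirical vs theoretical comparison -> summary report.

default_experiment_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    grid = list(from = 25, to = 425, by = 50),
    n_shuffles = 20,
    alpha = 0.05,
    threshold = 0.8,
    min_denominator = 10,
    model = list(
      n_outer = 5, n_inner = 5, sided = "one", inner_score = "r2",
      pooling = "fold-centered", strategy = "refit"
    ),
    theory = list(sided = "two", target_prob = 0.8, n_max = 1000),
    metrics = "SC",
    synthetic = list(
      n_subjects = 900,
      n_nodes = 25,
      feature_model = "sparse-lognormal",
      n_informative = NULL,
      reliability = 1,
      confound_weight = 0,
      phenotypes = list(
        list(name = "pheno_r2_0.04", true_r2 = 0.04, category = "trait")
      )
    )
  )
}

read_experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  cfg <- modifyList(default_experiment_config(), config)
  # modifyList merges by name only; the phenotype list is unnamed and must be
  # replaced wholesale
  if (!is.null(config$synthetic$phenotypes)) {
    cfg$synthetic$phenotypes <- config$synthetic$phenotypes
  }
  ph <- cfg$synthetic$phenotypes
  if (length(ph) == 0) abort("config error at synthetic$phenotypes: need at least one phenotype")
  for (p in ph) {
    if (is.null(p$name) || is.null(p$true_r2)) {
      abort("config error at synthetic$phenotypes: each entry needs 'name' and 'true_r2'")
    }
  }
  grid <- cfg$grid
  if (!all(c("from", "to", "by") %in% names(grid))) {
    abort("config error at grid: need 'from', 'to', 'by'")
  }
  if (2 * grid$from > cfg$synthetic$n_subjects) {
    abort(sprintf(
      "sample-size error: smallest grid point %d needs %d subjects but only %d are configured",
      grid$from, 2 * grid$from, cfg$synthetic$n_subjects
    ))
  }
  cfg
}

#' Run a full replicability experiment from a config
#'
#' Generates a synthetic cohort per the config, runs the split-resample
#' engine for every phenotype and metric across the sample-size grid, derives
#' each phenotype's theoretical sample size from the mean replication-half
#' effect size at its empirical minimum replicable sample size, and writes
#' (optionally) the long-format records, per-curve summaries, the
#' empirical-theoretical comparison, a replicable-phenotype report and a run
#' manifest. Identical config and seed reproduce identical outputs.
#'
#' @param config A config list or path to a YAML config file. Keys (with
#'   defaults): `seed`, `out_dir`, `grid` (`from`/`to`/`by`), `n_shuffles`,
#'   `alpha`, `threshold`, `model` (`n_outer`, `n_inner`, `sided`,
#'   `strategy`), `theory` (`sided`, `target_prob`, `n_max`), `metrics`, and
#'   `synthetic` (`n_subjects`, `n_nodes`, `feature_model`, `n_informative`,
#'   `reliability`, `confound_weight`, `phenotypes` — a list of
#'   `name`/`true_r2`/optional `category` entries).
#' @param verbose Print progress.
#' @return An object of class `replication_experiment`: `curves` (named list
#'   of `replication_curve`s), `records`, `curve_summary`, `comparison`
#'   (per-phenotype `n_E`, `r_rep_at_n_E`, `n_T`, plus the correlation when
#'   at least 3 finite pairs exist), `report` (from [report_summary()]),
#'   `manifest`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  cfg <- read_experiment_config(config)
  t0 <- Sys.time()
  syn <- cfg$synthetic
  grid <- seq(cfg$grid$from, cfg$grid$to, by = cfg$grid$by)

  curves <- list()
  categories <- c()
  timings <- list()
  for (mi in seq_along(cfg$metrics)) {
    metric <- cfg$metrics[[mi]]
    for (pi in seq_along(syn$phenotypes)) {
      ph <- syn$phenotypes[[pi]]
      scfg <- synth_config(
        n_subjects = syn$n_subjects, n_nodes = syn$n_nodes,
        true_r2 = ph$true_r2,
        reliability = syn$reliability %||% 1,
        confound_weight = syn$confound_weight %||% 0,
        feature_model = syn$feature_model,
        n_informative = syn$n_informative,
        seed = derive_seed(cfg$seed, mi, pi)
      )
      feats <- generate_features(scfg)
      phen <- generate_phenotype(feats, scfg)
      t1 <- Sys.time()
      cv <- run_curve(
        feats, phen$phenotype,
        grid = grid, n_shuffles = cfg$n_shuffles,
        alpha = cfg$alpha, threshold = cfg$threshold,
        min_denominator = cfg$min_denominator,
        seed = derive_seed(cfg$seed, mi, pi, 1000),
        phenotype_name = ph$name, metric = metric,
        n_outer = cfg$model$n_outer, n_inner = cfg$model$n_inner,
        sided = cfg$model$sided, inner_score = cfg$model$inner_score,
        pooling = cfg$model$pooling, strategy = cfg$model$strategy,
        verbose = verbose
      )
      timings[[paste(metric, ph$name, sep = "/")]] <-
        as.numeric(difftime(Sys.time(), t1, units = "secs"))
      curves[[paste(metric, ph$name, sep = "/")]] <- cv
      categories[ph$name] <- ph$category %||% "unspecified"
      if (verbose) inform(sprintf("finished %s / %s", metric, ph$name))
    }
  }

  records <- purrr::map_dfr(curves, "records")
  curve_summary <- purrr::map_dfr(curves, function(cv) {
    dplyr::mutate(cv$summary,
      phenotype = cv$phenotype, metric = cv$metric, n_E = cv$n_E,
      .before = 1
    )
  })

  comparison <- purrr::map_dfr(curves, function(cv) {
    r_at <- if (is.na(cv$n_E)) {
      NA_real_
    } else {
      cv$summary$mean_r_rep[cv$summary$n == cv$n_E]
    }
    nt <- if (is.na(r_at) || r_at <= 0) {
      NA_integer_
    } else {
      theoretical_n(
        r_at,
        alpha = cfg$alpha, target_prob = cfg$theory$target_prob,
        n_max = cfg$theory$n_max, sided = cfg$theory$sided
      )$n_T
    }
    tibble::tibble(
      phenotype = cv$phenotype, metric = cv$metric,
      n_E = cv$n_E, r_rep_at_n_E = r_at, n_T = nt
    )
  })
  cmp_cor <- NA_real_
  if (sum(is.finite(comparison$n_E) & is.finite(comparison$n_T)) >= 3) {
    cmp_cor <- compare_empirical_theoretical(comparison)$correlation
  }

  report <- report_summary(
    curves,
    categories = categories, threshold = cfg$threshold
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("repliconn")),
    config = cfg,
    seed = cfg$seed,
    theory_sidedness = cfg$theory$sided,
    model_sidedness = cfg$model$sided,
    grid = grid,
    timings_sec = timings,
    started = format(t0), finished = format(Sys.time())
  )

  out <- structure(
    list(
      curves = curves, records = records, curve_summary = curve_summary,
      comparison = comparison, comparison_correlation = cmp_cor,
      report = report, categories = categories, manifest = manifest,
      config = cfg
    ),
    class = "replication_experiment"
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(records, file.path(cfg$out_dir, "records.tsv"), progress = FALSE)
    readr::write_tsv(curve_summary, file.path(cfg$out_dir, "curves.tsv"), progress = FALSE)
    readr::write_tsv(comparison, file.path(cfg$out_dir, "comparison.tsv"), progress = FALSE)
    readr::write_tsv(report, file.path(cfg$out_dir, "report.tsv"), progress = FALSE)
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  }
  out
}

#' @export
print.replication_experiment <- function(x, ...) {
  cat(sprintf(
    "<replication_experiment> %d curve(s), %d phenotype(s), grid %s\n",
    length(x$curves), length(unique(x$records$phenotype)),
    paste(range(x$manifest$grid), collapse = "-")
  ))
  if (!is.na(x$comparison_correlation)) {
    cat(sprintf("  empirical vs theoretical n: r = %.3f\n", x$comparison_correlation))
  }
  print(x$report)
  invisible(x)
}

#' Replicable-phenotype summary report
#'
#' Fraction of phenotypes whose association replicates (reaches the
#' replicability threshold within the grid), per metric and under the
#' union-across-metrics rule, split by trait/state category. Counts are
#' reported as `"k/N (pct%)"` with percentages rounded half-up; an empty
#' category is reported as `NA`, not 0%.
#'
#' @param curves A `replication_experiment`, or a list of
#'   `replication_curve`s.
#' @param categories Named character vector phenotype -> category
#'   (`"trait"`, `"state"` or `"unspecified"`); unnamed phenotypes count as
#'   unspecified.
#' @param threshold Replicability threshold (default 0.8).
#' @return A tibble with columns `scope` (metric name or `"union"`),
#'   `category` (`"all"`, `"trait"`, `"state"`), `replicable`, `total`,
#'   `pct`, `label`.
#' @export
report_summary <- function(curves, categories = NULL, threshold = 0.8) {
  if (inherits(curves, "replication_experiment")) {
    categories <- categories %||% curves$categories
    curves <- curves$curves
  }
  stopifnot(length(curves) >= 1)
  per_curve <- purrr::map_dfr(curves, function(cv) {
    tibble::tibble(
      phenotype = cv$phenotype, metric = cv$metric,
      n_E = min_replicable_n(cv,
        threshold = threshold,
        min_denominator = cv$min_denominator %||% 10
      )
    )
  })
  phenos <- unique(per_curve$phenotype)
  cats <- setNames(rep("unspecified", length(phenos)), phenos)
  if (!is.null(categories)) {
    known <- intersect(names(categories), phenos)
    cats[known] <- categories[known]
  }

  union_tab <- per_curve |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::summarise(replicable = any(!is.na(.data$n_E)), .groups = "drop") |>
    dplyr::mutate(metric = "union")
  metric_tab <- per_curve |>
    dplyr::mutate(replicable = !is.na(.data$n_E)) |>
    dplyr::select("phenotype", "metric", "replicable")
  full <- dplyr::bind_rows(metric_tab, union_tab) |>
    dplyr::mutate(category = unname(cats[.data$phenotype]))

  cell <- function(d) {
    k <- sum(d$replicable)
    n <- nrow(d)
    if (n == 0) {
      tibble::tibble(
        replicable = NA_integer_, total = 0L, pct = NA_real_, label = "n/a"
      )
    } else {
      pct <- round_half_up(100 * k / n)
      tibble::tibble(
        replicable = as.integer(k), total = as.integer(n), pct = pct,
        label = sprintf("%d/%d (%d%%)", k, n, as.integer(pct))
      )
    }
  }
  scopes <- unique(full$metric)
  out <- purrr::map_dfr(scopes, function(sc) {
    d <- full[full$metric == sc, ]
    dplyr::bind_rows(
      dplyr::mutate(cell(d), scope = sc, category = "all"),
      dplyr::mutate(cell(d[d$category == "trait", ]), scope = sc, category = "trait"),
      dplyr::mutate(cell(d[d$category == "state", ]), scope = sc, category = "state")
    )
  })
  dplyr::select(out, "scope", "category", "replicable", "total", "pct", "label")
}
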