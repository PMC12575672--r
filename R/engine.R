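# The split-resample replication experiment: repeated disjoint
# discovery/replication splits across a sample-size grid, aggregated into a
# replication-probability curve per phenotype.

#' Draw one disjoint discovery/replication split
#'
#' Two disjoint subject sets of size `n` each are drawn uniformly at random
#' without replacement — no demographic matching or stratification, so the
#' replication half plays the role of an arbitrary unseen sample from the
#' same population.
#'
#' @param subjects Vector of subject ids, or a single integer N (ids `1:N`).
#' @param n Per-half sample size; `2 * n` must not exceed the cohort size.
#' @param seed Optional integer seed (caller's RNG untouched when given).
#' @return A list of class `split_pair` with `discovery` and `replication`.
#' @examples
#' draw_split(900, 425, seed = 1)
#' @export
draw_split <- function(subjects, n, seed = NULL) {
  if (length(subjects) == 1 && is.numeric(subjects)) {
    subjects <- seq_len(subjects)
  }
  N <- length(subjects)
  if (2 * n > N) {
    abort(sprintf("sample-size error: 2 * n = %d exceeds cohort size %d", 2 * n, N))
  }
  picked <- with_local_seed(seed, sample(subjects, 2 * n, replace = FALSE))
  structure(
    list(
      discovery = picked[seq_len(n)],
      replication = picked[n + seq_len(n)]
    ),
    class = "split_pair"
  )
}

#' Replication probability from a set of shuffle records
#'
#' The probability that the association is significant in the replication
#' half, among shuffles where it was significant in the discovery half:
#' `#{p_rep < alpha & p_dis < alpha} / #{p_dis < alpha}`. When no shuffle is
#' discovery-significant the probability is undefined and `NA` is returned —
#' never 0, since "we could not even discover the effect" and "the effect
#' does not replicate" must not be conflated.
#'
#' @param records Data frame with columns `p_dis` and `p_rep` (and optionally
#'   `n`, which must then be constant).
#' @param alpha Significance level (default 0.05).
#' @param min_denominator Denominators below this raise a low-confidence
#'   warning (default 10).
#' @return A single probability in `[0, 1]`, or `NA` if undefined, with
#'   attributes `n_discovery_significant` and `n_both_significant`.
#' @examples
#' rec <- tibble::tibble(p_dis = c(0.01, 0.2, 0.03), p_rep = c(0.04, 0.9, 0.8))
#' estimate_p_replicability(rec)
#' @export
estimate_p_replicability <- function(records, alpha = 0.05, min_denominator = 10) {
  stopifnot(is.data.frame(records), all(c("p_dis", "p_rep") %in% names(records)))
  if (nrow(records) < 1) abort("estimate_p_replicability() needs at least one record")
  if ("n" %in% names(records) && length(unique(records$n)) > 1) {
    abort("aggregation error: records mix different sample sizes n")
  }
  dis <- records$p_dis < alpha
  both <- dis & records$p_rep < alpha
  den <- sum(dis)
  p <- if (den == 0) NA_real_ else sum(both) / den
  if (den > 0 && den < min_denominator) {
    warn(sprintf(
      "low-confidence P_replicability: only %d discovery-significant shuffle(s)", den
    ))
  }
  structure(p,
    n_discovery_significant = den,
    n_both_significant = sum(both)
  )
}

#' Run the split-resample experiment across a sample-size grid
#'
#' For every sample size `n` on the grid and every shuffle, a disjoint
#' discovery/replication split is drawn, a ridge model is fit on the
#' discovery half under nested cross-validation, refit on the full discovery
#' half and evaluated on the replication half; the per-shuffle outcomes
#' (`r_dis`, `p_dis`, `r_rep`, `p_rep`) are aggregated into a replication
#' probability per sample size and the minimum replicable sample size.
#'
#' Each (sample size, shuffle) cell gets its own seed derived from the master
#' seed, so any cell is reproducible in isolation and records may be computed
#' or appended in any order. If `record_file` is given, records are appended
#' to it as they are produced and an interrupted run resumes from what is
#' already on disk.
#'
#' @param features Feature table (tibble with `subject_id`) or matrix.
#' @param phenotype Target: numeric vector or phenotype table.
#' @param grid Ascending per-half sample sizes (default `seq(25, 425, 25)`).
#'   Entries with `2 * n` beyond the cohort are dropped with a warning.
#' @param n_shuffles Splits per sample size (default 100).
#' @param alpha Significance level for both halves (default 0.05).
#' @param threshold Replicability threshold defining the minimum replicable
#'   sample size (strictly greater than; default 0.8).
#' @param min_denominator Minimum discovery-significant count for an n_E
#'   crossing (see [min_replicable_n()]; default 10).
#' @param seed Master seed (default 1).
#' @param phenotype_name,metric Labels carried into the records.
#' @param n_outer,n_inner,alpha_grid,sided,inner_score,pooling,strategy Passed
#'   to the model stage; see [fit_nested_cv()] and [refit_and_evaluate()].
#' @param record_file Optional TSV path for incremental persistence.
#' @param verbose Print one line per grid point.
#' @return An object of class `replication_curve`: `records` (long tibble, one
#'   row per shuffle), `summary` (per-n tibble with `p_replicability`,
#'   `mean_r_dis`, `mean_r_rep`, `delta_r`), and `n_E`.
#' @export
run_curve <- function(features, phenotype,
                      grid = seq(25, 425, by = 25),
                      n_shuffles = 100,
                      alpha = 0.05,
                      threshold = 0.8,
                      min_denominator = 10,
                      seed = 1,
                      phenotype_name = "phenotype",
                      metric = "SC",
                      n_outer = 5, n_inner = 5,
                      alpha_grid = default_alpha_grid(),
                      sided = c("one", "two"),
                      inner_score = c("r2", "cor"),
                      pooling = c("fold-centered", "fold-standardized", "raw"),
                      strategy = c("refit", "outer-ensemble-mean"),
                      record_file = NULL,
                      verbose = FALSE) {
  sided <- match.arg(sided)
  inner_score <- match.arg(inner_score)
  pooling <- match.arg(pooling)
  strategy <- match.arg(strategy)
  fm <- as_feature_matrix(features)
  yv <- as_response(phenotype, fm$ids)
  N <- nrow(fm$X)
  grid <- sort(unique(as.integer(grid)))
  if (any(2 * grid > N)) {
    warn(sprintf(
      "grid truncated: sample sizes {%s} need more than the %d available subjects",
      paste(grid[2 * grid > N], collapse = ", "), N
    ))
    grid <- grid[2 * grid <= N]
  }
  if (length(grid) == 0) abort("sample-size grid is empty after truncation")

  done <- NULL
  if (!is.null(record_file) && file.exists(record_file)) {
    done <- readr::read_tsv(record_file, show_col_types = FALSE, progress = FALSE)
    done <- done[done$phenotype == phenotype_name & done$metric == metric, ]
  }

  rows <- vector("list", length(grid) * n_shuffles)
  k <- 0
  for (gi in seq_along(grid)) {
    nn <- grid[gi]
    for (sh in seq_len(n_shuffles)) {
      k <- k + 1
      if (!is.null(done) && nrow(done) > 0 &&
        any(done$n == nn & done$shuffle == sh)) {
        rows[[k]] <- done[done$n == nn & done$shuffle == sh, ][1, ]
        next
      }
      child <- derive_seed(seed, gi, nn, sh)
      split <- draw_split(seq_len(N), nn, seed = child)
      Xd <- fm$X[split$discovery, , drop = FALSE]
      Xr <- fm$X[split$replication, , drop = FALSE]
      fit <- fit_nested_cv(
        Xd, yv[split$discovery],
        n_outer = n_outer, n_inner = n_inner, alpha_grid = alpha_grid,
        seed = derive_seed(child, 1), sided = sided,
        inner_score = inner_score, pooling = pooling,
        keep_models = (strategy == "outer-ensemble-mean")
      )
      rep_ <- refit_and_evaluate(
        Xd, yv[split$discovery], fit, Xr, yv[split$replication],
        sided = sided, strategy = strategy
      )
      rec <- tibble::tibble(
        phenotype = phenotype_name, metric = metric,
        n = nn, shuffle = sh, seed = child,
        r_dis = fit$r_dis, p_dis = fit$p_dis,
        r_rep = rep_$r_rep, p_rep = rep_$p_rep,
        selected_alpha = fit$selected_alpha
      )
      rows[[k]] <- rec
      if (!is.null(record_file)) {
        readr::write_tsv(rec, record_file,
          append = file.exists(record_file), progress = FALSE
        )
      }
    }
    if (verbose) {
      inform(sprintf("%s/%s n = %d: %d shuffles done", phenotype_name, metric, nn, n_shuffles))
    }
  }
  records <- dplyr::bind_rows(rows)
  new_replication_curve(records, phenotype_name, metric, grid, n_shuffles,
    alpha = alpha, threshold = threshold,
    min_denominator = min_denominator, seed = seed
  )
}

# Aggregate long-format records into a replication_curve object.
new_replication_curve <- function(records, phenotype_name, metric, grid,
                                  n_shuffles, alpha = 0.05, threshold = 0.8,
                                  min_denominator = 10, seed = NA_integer_) {
  summary <- records |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(
      n_shuffles = dplyr::n(),
      n_dis_sig = sum(.data$p_dis < alpha),
      n_both_sig = sum(.data$p_dis < alpha & .data$p_rep < alpha),
      mean_r_dis = mean(.data$r_dis, na.rm = TRUE),
      mean_r_rep = mean(.data$r_rep, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_replicability = dplyr::if_else(
        .data$n_dis_sig == 0, NA_real_, .data$n_both_sig / .data$n_dis_sig
      ),
      delta_r = .data$mean_r_dis - .data$mean_r_rep
    ) |>
    dplyr::arrange(.data$n)
  curve <- structure(
    list(
      records = records, summary = summary,
      phenotype = phenotype_name, metric = metric,
      grid = grid, n_shuffles = n_shuffles,
      alpha = alpha, threshold = threshold,
      min_denominator = min_denominator, seed = seed,
      n_E = NA_integer_
    ),
    class = "replication_curve"
  )
  curve$n_E <- min_replicable_n(curve,
    threshold = threshold, min_denominator = min_denominator
  )
  curve
}

#' @export
print.replication_curve <- function(x, ...) {
  cat(sprintf(
    "<replication_curve> %s / %s: %d sample sizes x %d shuffles, alpha = %g\n",
    x$phenotype, x$metric, length(x$grid), x$n_shuffles, x$alpha
  ))
  if (is.na(x$n_E)) {
    cat(sprintf("  not replicable (P <= %g) at any n up to %d\n", x$threshold, max(x$grid)))
  } else {
    cat(sprintf("  minimum replicable sample size n_E = %d (P > %g)\n", x$n_E, x$threshold))
  }
  invisible(x)
}

#' Minimum replicable sample size of a curve
#'
#' The smallest grid sample size whose replication probability strictly
#' exceeds `threshold`. Undefined probabilities (no discovery-significant
#' shuffle) count as failing, and so do low-confidence ones: when the summary
#' carries the discovery-significant count (`n_dis_sig`), a threshold
#' crossing only qualifies if its denominator reaches `min_denominator` —
#' otherwise a single lucky shuffle (a 1/1 = 100% "probability") would set
#' the minimum replicable sample size. Returns `NA` — the "not replicable at
#' the maximum investigated sample size" sentinel — when no grid point
#' qualifies.
#'
#' @param curve A `replication_curve`, or its per-n summary tibble (columns
#'   `n`, `p_replicability`, optionally `n_dis_sig`).
#' @param threshold Replicability threshold (default 0.8, strict).
#' @param min_denominator Minimum number of discovery-significant shuffles
#'   for a crossing to count (default 10; only enforced when the summary
#'   records denominators).
#' @return Integer sample size, or `NA_integer_`.
#' @examples
#' s <- tibble::tibble(n = c(25, 50, 75), p_replicability = c(0.3, 0.85, 0.9))
#' min_replicable_n(s)
#' @export
min_replicable_n <- function(curve, threshold = 0.8, min_denominator = 10) {
  s <- if (inherits(curve, "replication_curve")) curve$summary else curve
  stopifnot(is.data.frame(s), all(c("n", "p_replicability") %in% names(s)))
  if (nrow(s) == 0) abort("empty curve")
  s <- s[order(s$n), ]
  ok <- !is.na(s$p_replicability) & s$p_replicability > threshold
  if ("n_dis_sig" %in% names(s)) {
    ok <- ok & s$n_dis_sig >= min_denominator
  }
  if (!any(ok)) NA_integer_ else as.integer(s$n[which(ok)[1]])
}

#' Union replicability across connectome metrics
#'
#' A phenotype counts as replicable when at least one metric's curve reaches
#' the replicability threshold within the investigated grid.
#'
#' @param curves List of `replication_curve` objects (one per metric) for a
#'   single phenotype.
#' @param threshold Replicability threshold (default 0.8).
#' @return A list with `replicable` (logical), `contributing` (tibble of
#'   metrics that replicate, with their `n_E`), and `n_E` (the smallest
#'   contributing `n_E`, or `NA`).
#' @export
union_replicability <- function(curves, threshold = 0.8) {
  stopifnot(length(curves) >= 1)
  tab <- purrr::map_dfr(curves, function(cv) {
    tibble::tibble(
      metric = cv$metric,
      n_E = min_replicable_n(cv,
        threshold = threshold,
        min_denominator = cv$min_denominator %||% 10
      )
    )
  })
  contributing <- tab[!is.na(tab$n_E), ]
  list(
    replicable = nrow(contributing) > 0,
    contributing = contributing,
    n_E = if (nrow(contributing) > 0) min(contributing$n_E) else NA_integer_
  )
}

#' Effect-size summary of a replication curve
#'
#' Tabulates, per sample size, the mean discovery and replication effect
#' sizes, their difference `delta_r = mean(r_dis) - mean(r_rep)` and their
#' average, plus the correlation between discovery and replication effect
#' sizes across the grid (how well effect-size magnitude replicates,
#' independent of any significance threshold).
#'
#' @param curve A `replication_curve`.
#' @return A tibble with one row per sample size and attribute `cor_dis_rep`
#'   (`NA` when the grid has fewer than 2 usable points).
#' @export
summarize_effects <- function(curve) {
  stopifnot(inherits(curve, "replication_curve"))
  if (nrow(curve$records) == 0) abort("curve has no records")
  tab <- curve$summary |>
    dplyr::transmute(
      n = .data$n,
      mean_r_dis = .data$mean_r_dis,
      mean_r_rep = .data$mean_r_rep,
      delta_r = .data$delta_r,
      mean_r = (.data$mean_r_dis + .data$mean_r_rep) / 2
    )
  ok <- stats::complete.cases(tab[, c("mean_r_dis", "mean_r_rep")])
  cc <- if (sum(ok) >= 2) safe_cor(tab$mean_r_dis[ok], tab$mean_r_rep[ok]) else NA_real_
  attr(tab, "cor_dis_rep") <- cc
  tab
}
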