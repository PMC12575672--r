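test_that("splits are disjoint, sized, uniform draws", {
  sp <- draw_split(900, 425, seed = 1)
  expect_length(sp$discovery, 425)
  expect_length(sp$replication, 425)
  expect_length(intersect(sp$discovery, sp$replication), 0)
  expect_length(union(sp$discovery, sp$replication), 850)

  full <- draw_split(50, 25, seed = 2)
  expect_setequal(union(full$discovery, full$replication), 1:50)

  expect_identical(draw_split(100, 40, seed = 9), draw_split(100, 40, seed = 9))
  expect_error(draw_split(100, 51), "sample-size error")
})

test_that("replication probability is the conditional fraction, never conflating undefined with zero", {
  all_sig <- make_records(100, 100, 100)
  expect_equal(as.numeric(estimate_p_replicability(all_sig)), 1.0)

  part <- make_records(80, 60, 100)
  expect_equal(as.numeric(estimate_p_replicability(part)), 0.75)

  none <- make_records(0, 0, 50)
  p0 <- estimate_p_replicability(none)
  expect_true(is.na(p0))
  expect_equal(attr(p0, "n_discovery_significant"), 0)

  expect_warning(
    p_low <- estimate_p_replicability(make_records(3, 3, 50)),
    "low-confidence"
  )
  expect_equal(as.numeric(p_low), 1)

  mixed <- dplyr::bind_rows(make_records(5, 5, 10, n = 50), make_records(5, 5, 10, n = 100))
  expect_error(estimate_p_replicability(mixed), "aggregation error")
})

test_that("replication probability is invariant to record order and relabeling", {
  set.seed(71)
  rec <- make_records(40, 22, 60)
  p1 <- as.numeric(estimate_p_replicability(rec))
  p2 <- as.numeric(estimate_p_replicability(rec[sample(nrow(rec)), ]))
  expect_equal(p1, p2)
})

test_that("minimum replicable n takes the first strict threshold crossing", {
  s <- tibble::tibble(n = c(25, 50, 75), p_replicability = c(0.3, 0.85, 0.9))
  expect_equal(min_replicable_n(s), 50L)
  expect_equal(
    min_replicable_n(tibble::tibble(n = c(25, 50), p_replicability = c(0.95, 0.2))),
    25L
  )
  expect_true(is.na(min_replicable_n(
    tibble::tibble(n = c(25, 50), p_replicability = c(0.8, 0.79))
  ))) # strict: exactly 0.8 does not qualify
  expect_true(is.na(min_replicable_n(
    tibble::tibble(n = c(25, 50), p_replicability = c(NA, 0.5))
  )))
  # undefined entries fail but later crossings still count
  expect_equal(
    min_replicable_n(tibble::tibble(n = c(25, 50), p_replicability = c(NA, 0.9))),
    50L
  )
})

test_that("a phenotype replicates under the union rule if any metric replicates", {
  mk <- function(metric, ps) {
    rec <- dplyr::bind_rows(lapply(seq_along(ps), function(i) {
      dplyr::mutate(make_records(20, round(20 * ps[i]), 20, n = c(25, 50, 75)[i]))
    }))
    repliconn:::new_replication_curve(rec, "ph", metric,
      grid = c(25, 50, 75),
      n_shuffles = 20
    )
  }
  c_yes <- mk("SC", c(0.2, 0.9, 0.95))
  c_no <- mk("FA", c(0.1, 0.2, 0.3))
  u <- union_replicability(list(c_yes, c_no))
  expect_true(u$replicable)
  expect_equal(u$contributing$metric, "SC")
  expect_equal(u$n_E, 50L)

  u2 <- union_replicability(list(c_no))
  expect_false(u2$replicable)
  expect_true(is.na(u2$n_E))

  c_yes2 <- mk("RD", c(0.85, 0.9, 0.95))
  u3 <- union_replicability(list(c_yes, c_yes2))
  expect_setequal(u3$contributing$metric, c("SC", "RD"))
  expect_equal(u3$n_E, 25L)
})

test_that("effect-size summary tabulates delta_r and the cross-n correlation", {
  rec <- tibble::tibble(
    n = rep(c(25, 50, 75), each = 4),
    shuffle = rep(1:4, 3),
    p_dis = 0.01, p_rep = 0.01,
    r_dis = rep(c(0.1, 0.2, 0.3), each = 4),
    r_rep = rep(c(0.1, 0.2, 0.3), each = 4)
  )
  cv <- repliconn:::new_replication_curve(rec, "ph", "SC", c(25, 50, 75), 4)
  se <- summarize_effects(cv)
  expect_equal(se$delta_r, rep(0, 3))
  expect_equal(attr(se, "cor_dis_rep"), 1)
  expect_equal(se$mean_r, se$mean_r_dis)

  rec2 <- dplyr::mutate(rec, r_rep = rep(c(0.3, 0.2, 0.1), each = 4))
  se2 <- summarize_effects(repliconn:::new_replication_curve(rec2, "ph", "SC", c(25, 50, 75), 4))
  expect_equal(attr(se2, "cor_dis_rep"), -1)
})

test_that("run_curve saturates immediately on a noiseless phenotype", {
  set.seed(81)
  d <- make_linear_dataset(80, 6, k = 3, noise = 0)
  cv <- run_curve(d$X, d$y,
    grid = c(15, 30), n_shuffles = 5, min_denominator = 5, seed = 4,
    phenotype_name = "noiseless"
  )
  expect_equal(cv$summary$p_replicability, c(1, 1))
  expect_equal(cv$n_E, 15L)
  expect_equal(nrow(cv$records), 10)
  expect_identical(
    tidy(cv),
    tidy(run_curve(d$X, d$y,
      grid = c(15, 30), n_shuffles = 5, min_denominator = 5, seed = 4,
      phenotype_name = "noiseless"
    ))
  )
})

test_that("run_curve truncates an infeasible grid with a warning", {
  set.seed(82)
  d <- make_linear_dataset(40, 5, noise = 0)
  expect_warning(
    cv <- run_curve(d$X, d$y, grid = c(15, 30), n_shuffles = 3, seed = 1),
    "truncated"
  )
  expect_equal(cv$grid, 15L)
  expect_error(
    suppressWarnings(run_curve(d$X, d$y, grid = 100, n_shuffles = 2)),
    "empty"
  )
})

test_that("interrupted curve runs resume from the record file", {
  set.seed(83)
  d <- make_linear_dataset(60, 5, k = 2, noise = 0.3)
  dir <- withr::local_tempdir()
  rf <- file.path(dir, "records.tsv")
  cv1 <- run_curve(d$X, d$y,
    grid = c(10, 20), n_shuffles = 4, seed = 6,
    record_file = rf, phenotype_name = "ph"
  )
  n_rows_after_full <- nrow(readr::read_tsv(rf, show_col_types = FALSE))
  expect_equal(n_rows_after_full, 8)
  # resume: nothing recomputed, nothing re-appended, identical result
  cv2 <- run_curve(d$X, d$y,
    grid = c(10, 20), n_shuffles = 4, seed = 6,
    record_file = rf, phenotype_name = "ph"
  )
  expect_equal(nrow(readr::read_tsv(rf, show_col_types = FALSE)), n_rows_after_full)
  expect_equal(cv2$records$r_dis, cv1$records$r_dis)
  expect_equal(cv2$summary, cv1$summary)
})

test_that("per-cell seeds make shuffles independently reproducible", {
  # the same (n, shuffle) cell must yield the same split regardless of which
  # other cells are computed
  s1 <- derive_seed(5, 1, 25, 3)
  s2 <- derive_seed(5, 1, 25, 3)
  expect_identical(s1, s2)
  expect_false(derive_seed(5, 1, 25, 3) == derive_seed(5, 1, 25, 4))
  expect_false(derive_seed(5, 1, 25, 3) == derive_seed(5, 2, 25, 3))
  expect_true(all(vapply(1:200, function(i) derive_seed(1, i), integer(1)) > 0))
})

test_that("low-confidence threshold crossings do not set the minimum replicable n", {
  s1 <- tibble::tibble(
    n = c(25, 50, 75),
    p_replicability = c(1, 0.5, 0.9),
    n_dis_sig = c(1, 12, 15)
  )
  expect_equal(min_replicable_n(s1), 75L) # the 1/1 fluke at n = 25 is ignored
  expect_equal(min_replicable_n(s1, min_denominator = 1), 25L)
  # without denominators the spec-literal definition applies
  expect_equal(
    min_replicable_n(tibble::tibble(n = c(25, 50), p_replicability = c(1, 0.9))),
    25L
  )
})
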