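tiny_config <- function(dir = NULL, seed = 3) {
  list(
    seed = seed,
    out_dir = dir,
    grid = list(from = 15, to = 30, by = 15),
    n_shuffles = 4,
    min_denominator = 4,
    synthetic = list(
      n_subjects = 80, n_nodes = 4, feature_model = "dense-gaussian",
      phenotypes = list(
        list(name = "strong", true_r2 = 0.9, category = "trait"),
        list(name = "null", true_r2 = 0, category = "state")
      )
    )
  )
}

test_that("an experiment produces one curve row per phenotype, metric and grid point", {
  ex <- run_experiment(tiny_config())
  expect_s3_class(ex, "replication_experiment")
  expect_equal(nrow(ex$curve_summary), 2 * 1 * 2)
  expect_equal(nrow(ex$records), 2 * 1 * 2 * 4)
  expect_setequal(unique(ex$records$phenotype), c("strong", "null"))
  g <- glance(ex)
  expect_equal(g$n_curves, 2L)
})

test_that("experiments are reproducible and write their outputs", {
  dir <- withr::local_tempdir()
  ex1 <- run_experiment(tiny_config(dir = file.path(dir, "run1")))
  ex2 <- run_experiment(tiny_config(dir = file.path(dir, "run2")))
  expect_identical(ex1$curve_summary, ex2$curve_summary)
  expect_identical(ex1$report, ex2$report)
  r1 <- readr::read_tsv(file.path(dir, "run1", "records.tsv"), show_col_types = FALSE)
  r2 <- readr::read_tsv(file.path(dir, "run2", "records.tsv"), show_col_types = FALSE)
  expect_identical(r1, r2)
  expect_true(file.exists(file.path(dir, "run1", "manifest.yaml")))
  man <- yaml::read_yaml(file.path(dir, "run1", "manifest.yaml"))
  expect_equal(man$seed, 3)
  # a different seed changes the records
  ex3 <- run_experiment(tiny_config(seed = 4))
  expect_false(identical(ex1$records$r_dis, ex3$records$r_dis))
})

test_that("configs from YAML files behave like lists and bad configs fail fast", {
  dir <- withr::local_tempdir()
  cfgfile <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(tiny_config(), cfgfile)
  ex <- run_experiment(cfgfile)
  expect_equal(nrow(ex$curve_summary), 4)

  bad <- tiny_config()
  bad$grid$from <- 50 # 2 * 50 > 80 subjects
  bad$grid$to <- 50
  expect_error(run_experiment(bad), "sample-size error")

  bad2 <- tiny_config()
  bad2$synthetic$phenotypes <- list(list(name = "x"))
  expect_error(run_experiment(bad2), "config error")

  expect_error(run_experiment("/no/such/file.yaml"), "not found")
})

test_that("the summary report counts replicable phenotypes by category", {
  ex <- run_experiment(tiny_config())
  rep_tab <- ex$report
  # counts must equal a direct recount from the curves
  expected_all <- sum(vapply(ex$curves, function(cv) !is.na(cv$n_E), logical(1)))
  got <- rep_tab$replicable[rep_tab$scope == "SC" & rep_tab$category == "all"]
  expect_equal(got, expected_all)
  # the noiseless-strong phenotype replicates, the null one does not
  expect_equal(
    rep_tab$label[rep_tab$scope == "union" & rep_tab$category == "all"],
    "1/2 (50%)"
  )
  expect_equal(
    rep_tab$label[rep_tab$scope == "union" & rep_tab$category == "trait"],
    "1/1 (100%)"
  )
  expect_equal(
    rep_tab$label[rep_tab$scope == "union" & rep_tab$category == "state"],
    "0/1 (0%)"
  )
})

test_that("an empty trait/state category reports n/a, not 0%", {
  rec <- make_records(10, 9, 10, n = 25)
  cv <- repliconn:::new_replication_curve(rec, "ph", "SC", 25, 10)
  out <- report_summary(list(cv), categories = c(ph = "trait"))
  expect_true(all(out$label[out$category == "state"] == "n/a"))
  expect_true(all(is.na(out$pct[out$category == "state"])))
  expect_equal(out$label[out$scope == "union" & out$category == "all"], "1/1 (100%)")
})

test_that("percentages are rounded half-up in the paper-style labels", {
  recs <- lapply(1:3, function(i) {
    # 1 of 3 phenotypes replicable: 33.33 -> 33%
    k <- if (i == 1) 10 else 0
    cv <- repliconn:::new_replication_curve(
      make_records(10, k, 10, n = 25), paste0("p", i), "SC", 25, 10
    )
  })
  out <- report_summary(recs)
  expect_equal(out$pct[out$scope == "SC" & out$category == "all"], 33)
  expect_equal(repliconn:::round_half_up(36.5), 37)
  expect_equal(repliconn:::round_half_up(19.5), 20)
})
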