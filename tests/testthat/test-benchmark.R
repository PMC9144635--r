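small_replicates <- function() {
  simulate_replicates(n_samples = 25, n_metabolites = 12, seed = 51)
}

test_that("accuracy benchmark bookkeeping: one record per design cell", {
  rep <- run_accuracy_benchmark(
    small_replicates(), mechanisms = c("MCAR", "MIX"), rates = c(0.05, 0.1),
    methods = c("mean", "zero", "hm"), n_repeats = 2, seed = 3
  )
  expect_equal(nrow(rep$records), 2 * 2 * 2 * 3)
  expect_equal(nrow(rep$failures), 0)
  expect_true(all(rep$records$rmse >= 0))
  expect_true(all(c("cv_bin", "missingness_bin") %in% names(rep$per_metabolite)))
  expect_equal(nrow(rep$summary), 2 * 2 * 3)
})

test_that("benchmarks are a pure function of (config, seed)", {
  a <- run_accuracy_benchmark(small_replicates(), rates = 0.1,
                              methods = c("mean", "knn"), n_repeats = 2, seed = 7)
  b <- run_accuracy_benchmark(small_replicates(), rates = 0.1,
                              methods = c("mean", "knn"), n_repeats = 2, seed = 7)
  expect_equal(a$records, b$records)
  expect_equal(a$per_metabolite, b$per_metabolite)
  c <- run_accuracy_benchmark(small_replicates(), rates = 0.1,
                              methods = c("mean", "knn"), n_repeats = 2, seed = 8)
  expect_false(isTRUE(all.equal(a$records$rmse, c$records$rmse)))
})

test_that("the truth-passthrough oracle scores exactly zero everywhere", {
  rep <- run_accuracy_benchmark(small_replicates(), rates = c(0.1, 0.2),
                                methods = "oracle", n_repeats = 2, seed = 5)
  expect_true(all(rep$records$rmse == 0))
  expect_true(all(rep$records$percent_bias == 0))

  bio <- simulate_biological(n_samples = 20, n_metabolites = 12, seed = 6)
  rb <- run_regression_bias_assessment(bio, methods = "oracle", rates = 0.1,
                                       n_repeats = 2, seed = 6)
  expect_true(all(rb$regression$beta_diff == 0))
  expect_true(all(rb$regression$p_diff == 0))

  cons <- run_consistency_assessment(bio, methods = "oracle", rates = 0.1,
                                     n_repeats = 2, seed = 6)
  expect_true(all(cons$consistency$alpha_diff == 0))
})

test_that("zero-noise replicates make mean imputation exact", {
  tb <- simulate_replicates(n_samples = 20, n_metabolites = 8,
                            cv_range = c(1e-9, 1e-9), seed = 9)
  rep <- run_accuracy_benchmark(tb, rates = 0.1, methods = "mean",
                                n_repeats = 2, seed = 9)
  expect_true(all(rep$records$rmse < 1e-8))
})

test_that("consistency assessment produces one Wilcoxon matrix per rate x mechanism", {
  bio <- simulate_biological(n_samples = 20, n_metabolites = 15, seed = 7)
  rep <- run_consistency_assessment(
    bio, methods = c("mean", "hm"), rates = c(0.1, 0.2),
    mechanisms = c("MCAR", "MIX"), n_repeats = 3, seed = 4
  )
  expect_equal(length(rep$tests$wilcoxon_alpha_diff), 4)
  expect_true(all(vapply(rep$tests$wilcoxon_alpha_diff, dim, numeric(2)) == 2))
  expect_equal(nrow(rep$tests$t_alpha_diff), 2)
  expect_equal(
    sort(unique(rep$consistency$rate)), c(0.1, 0.2)
  )
})

test_that("regression assessment stratifies by injected metabolite missingness", {
  bio <- simulate_biological(n_samples = 24, n_metabolites = 15, seed = 8)
  rep <- run_regression_bias_assessment(
    bio, methods = c("mean", "grr"), rates = 0.15, n_repeats = 2, seed = 5
  )
  expect_equal(nrow(rep$regression), 15 * 2 * 2)
  expect_true(all(levels(rep$regression$missingness_bin) ==
                    c("[0,10]", "(10,20]", "(20,30]", "(30,100]")))
  expect_true(all(c("t_beta_diff", "t_abs_beta_diff", "t_p_diff",
                    "wilcoxon_abs_beta_diff") %in% names(rep$tests)))
  expect_true(all(rep$tests$t_beta_diff$p_fdr >= rep$tests$t_beta_diff$p - 1e-15))
})

test_that("in-depth protocol inserts distinct cells and bins percent bias", {
  bio <- simulate_biological(n_samples = 18, n_metabolites = 10,
                             baseline_missing_rate = 0.2, seed = 9)
  rep <- run_indepth_single_value(
    bio, n_iter = 12, seed = 3, method = "mean", sweep_rates = c(0.1, 0.3),
    sweep_repeats = 1
  )
  expect_equal(nrow(rep$records), 12)
  expect_equal(anyDuplicated(rep$records[, c("sample_id", "metabolite_id")]), 0L)
  expect_true(all(!is.na(rep$records$percent_bias)))
  expect_true(all(rep$summary$n > 0))
  expect_setequal(unique(rep$consistency$rate), c(0.1, 0.3))
  # sweep regressions exist because the table has an age covariate
  expect_gt(nrow(rep$regression), 0)

  expect_warning(
    run_indepth_single_value(bio, n_iter = 1e6, seed = 3, method = "mean",
                             sweep_rates = NULL),
    "capped"
  )
})

test_that("write_report writes the full file contract, even when empty", {
  dir <- withr::local_tempdir()
  rep <- run_accuracy_benchmark(small_replicates(), rates = 0.1,
                                methods = "mean", n_repeats = 1, seed = 2)
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("records.csv", "per_metabolite.csv", "consistency.csv",
           "regression.csv", "summary.csv", "tests.json", "provenance.json")
  ))))
  # empty sections are header-only or empty files, not absent
  expect_true(file.size(file.path(dir, "consistency.csv")) >= 0)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$experiment, "accuracy")
  expect_equal(prov$seed, 2)

  # provenance round trip: re-running the recorded config reproduces the report
  rep2 <- run_accuracy_benchmark(
    small_replicates(), mechanisms = unlist(prov$mechanisms),
    rates = unlist(prov$rates), methods = unlist(prov$methods),
    n_repeats = prov$n_repeats, seed = prov$seed
  )
  expect_equal(rep$records, rep2$records)
})

test_that("tidy, glance and autoplot expose report sections", {
  rep <- run_accuracy_benchmark(small_replicates(), rates = 0.1,
                                methods = c("mean", "hm"), n_repeats = 2, seed = 2)
  expect_identical(tidy(rep), rep$records)
  expect_equal(nrow(tidy(rep, "per_metabolite")), nrow(rep$per_metabolite))
  g <- glance(rep)
  expect_equal(g$n_records, 4)
  expect_equal(g$n_methods, 2)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")

  imp <- impute(random_log_table(n = 6, p = 4, n_miss = 4, seed = 1), "mean")
  expect_equal(nrow(tidy(imp)), 4)
  expect_equal(glance(imp)$method, "mean")
})
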