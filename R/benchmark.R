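# End-to-end experiment drivers. Every driver is a pure function of
# (data, config, seed): per-cell sub-seeds are derived from the master seed so
# any single cell can be replayed in isolation, and each cell failure is
# logged and skipped rather than aborting the run.

default_rates <- function() c(0.02, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70)

new_benchmark_report <- function(experiment, records,
                                 per_metabolite = tibble(),
                                 consistency = tibble(),
                                 regression = tibble(),
                                 summary = tibble(),
                                 tests = list(), provenance = list(),
                                 failures = tibble()) {
  structure(
    list(
      experiment = experiment, records = records,
      per_metabolite = per_metabolite, consistency = consistency,
      regression = regression, summary = summary, tests = tests,
      provenance = provenance, failures = failures
    ),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("# Benchmark report: %s (%d records, seed %s)\n",
              x$experiment, nrow(x$records),
              x$provenance$seed %||% "?"))
  if (nrow(x$failures)) {
    cat(sprintf("# %d cell(s) failed and were skipped\n", nrow(x$failures)))
  }
  invisible(x)
}

# log10 analysis table + raw-scale per-metabolite context
prepare_complete <- function(data) {
  if (table_scale(data) == "raw") data <- log10_transform(data)
  split_complete(data)$complete
}

# one-sample t that degrades to NA (instead of erroring) on zero-variance
# difference distributions, e.g. under the truth-passthrough oracle
safe_one_sample_t <- function(values, mu0 = 0) {
  tryCatch(one_sample_t(values, mu0), error = function(e) {
    tibble(estimate = mean(values), t = NA_real_, df = length(values) - 1,
           p = NA_real_)
  })
}

safe_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- fdr_adjust(p[ok])
  out
}

inject_any <- function(table, mechanism, rate, seed, chisq_df, pct_range) {
  switch(mechanism,
    MCAR = inject_mcar(table, rate, seed),
    MAR = inject_mar(table, rate, seed, pct_range = pct_range),
    MNAR = inject_mnar(table, rate, seed, chisq_df = chisq_df),
    MIX = inject_mixture(table, rate, seed, chisq_df = chisq_df,
                         pct_range = pct_range),
    abort(sprintf("Unknown mechanism '%s'.", mechanism))
  )
}

# "oracle" is a truth-passthrough pseudo-method used to validate the plumbing:
# it restores the masked truth, so every error metric is exactly zero
bench_impute <- function(masked, mask, method, params, seed) {
  if (identical(method, "oracle")) {
    truth <- restore_mask(masked, mask)
    return(new_imputation_result(masked, as_abund_matrix(truth), "oracle",
                                 seed = seed))
  }
  impute(masked, method, params = params, seed = seed)
}

bin_label <- function(x, breaks) {
  cut(x, breaks = breaks, include.lowest = TRUE, right = TRUE)
}

#' Accuracy benchmark: inject, impute, score
#'
#' The headline experiment: for every repeat x mechanism x rate x method
#' cell, missingness is injected into a complete table, imputed, and scored
#' by RMSE and percent bias over the masked cells (log10 scale). The same
#' mask is shared by all methods within a cell so method comparisons are
#' paired. Per-metabolite scores are also recorded, stratified by raw-scale
#' CV bin and injected-missingness bin, to support RMSE-on-CV and
#' RMSE-on-missingness regressions.
#'
#' @param data An [abundance_table()] (raw tables are log10-transformed and
#'   reduced to their complete metabolites first).
#' @param mechanisms Subset of `c("MCAR", "MAR", "MNAR", "MIX")`. The mixture
#'   is the default headline mechanism.
#' @param rates Global missingness rates in (0, 0.75].
#' @param methods Methods to score (see [imputation_methods()]); `"oracle"`
#'   is accepted as a truth-passthrough control.
#' @param n_repeats Injection repeats per condition.
#' @param seed Master seed.
#' @param chisq_df,pct_range Forwarded to the injectors.
#' @param method_params Optional named list of per-method parameter overrides,
#'   e.g. `list(rf = list(n_trees = 50))`.
#' @param cv_breaks,miss_breaks Stratification bin edges for CV and percent
#'   metabolite missingness.
#' @return A `benchmark_report` with `records`, `per_metabolite`, `summary`
#'   (median/IQR per condition) and provenance.
#' @export
run_accuracy_benchmark <- function(data, mechanisms = "MIX",
                                   rates = default_rates(),
                                   methods = imputation_methods()$method,
                                   n_repeats = 20, seed = 1, chisq_df = 6,
                                   pct_range = c(5, 50),
                                   method_params = list(),
                                   cv_breaks = c(0, 0.1, 0.2, 0.3, Inf),
                                   miss_breaks = c(0, 10, 20, 30, 45, 100)) {
  stopifnot(n_repeats >= 1, all(rates > 0 & rates <= 0.75))
  seed <- check_seed(seed)
  complete <- prepare_complete(data)
  cv_tbl <- summarize_metabolites(complete)[, c("metabolite_id", "cv")]
  grid <- tidyr::expand_grid(
    repeat_ = seq_len(n_repeats), mechanism = mechanisms, rate = rates
  )
  grid$cell_seed <- derive_seeds(seed, nrow(grid))
  records <- list(); per_met <- list(); failures <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- tryCatch({
      mask <- inject_any(complete, g$mechanism, g$rate, g$cell_seed,
                         chisq_df, pct_range)
      masked <- apply_mask(complete, mask)
      mseeds <- derive_seeds(g$cell_seed, length(methods))
      cell_rec <- list(); cell_met <- list()
      for (mi in seq_along(methods)) {
        method <- methods[mi]
        imp <- bench_impute(masked, mask, method,
                            method_params[[method]] %||% list(), mseeds[mi])
        v <- masked_values(complete, imp$imputed, mask)
        cell_rec[[method]] <- tibble(
          repeat_ = g$repeat_, mechanism = g$mechanism, rate = g$rate,
          method = method, seed = g$cell_seed,
          n_masked = nrow(v),
          rmse = sqrt(mean((v$imputed - v$truth)^2)),
          percent_bias = mean(100 * abs(v$imputed - v$truth) / abs(v$truth))
        )
        pm <- v |>
          group_by(.data$metabolite_id) |>
          summarise(
            n_masked = n(),
            rmse = sqrt(mean((.data$imputed - .data$truth)^2)),
            percent_bias = mean(100 * abs(.data$imputed - .data$truth) /
                                  abs(.data$truth)),
            .groups = "drop"
          ) |>
          left_join(cv_tbl, by = "metabolite_id") |>
          mutate(
            repeat_ = g$repeat_, mechanism = g$mechanism, rate = g$rate,
            method = method,
            pct_missing = 100 * .data$n_masked / nrow(complete),
            cv_bin = bin_label(.data$cv, cv_breaks),
            missingness_bin = bin_label(.data$pct_missing, miss_breaks)
          )
        cell_met[[method]] <- pm
      }
      list(rec = dplyr::bind_rows(cell_rec), met = dplyr::bind_rows(cell_met))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- tibble(
        repeat_ = g$repeat_, mechanism = g$mechanism, rate = g$rate,
        seed = g$cell_seed, message = conditionMessage(res)
      )
    } else {
      records[[i]] <- res$rec
      per_met[[i]] <- res$met
    }
  }
  records <- dplyr::bind_rows(records)
  summary <- if (nrow(records)) {
    records |>
      group_by(.data$mechanism, .data$rate, .data$method) |>
      summarise(
        median_rmse = stats::median(.data$rmse),
        iqr_rmse = stats::IQR(.data$rmse),
        median_pb = stats::median(.data$percent_bias),
        n = n(), .groups = "drop"
      )
  } else {
    tibble()
  }
  new_benchmark_report(
    "accuracy", records, per_metabolite = dplyr::bind_rows(per_met),
    summary = summary,
    provenance = list(
      experiment = "accuracy", mechanisms = mechanisms, rates = rates,
      methods = methods, n_repeats = n_repeats, seed = seed,
      chisq_df = chisq_df, pct_range = pct_range,
      version = as.character(utils::packageVersion("metabomiss"))
    ),
    failures = dplyr::bind_rows(failures)
  )
}

#' Internal-consistency assessment after imputation
#'
#' Injects missingness (by default at the 10% and 20% global rates), imputes
#' with each method, and records the difference between the imputed and true
#' Cronbach's alpha plus the mean sample-to-sample correlation. Across
#' methods, alpha differences are compared with pairwise Wilcoxon rank-sum
#' tests (one matrix per rate x mechanism) and each method's alpha
#' differences are tested for departure from zero with a one-sample t-test
#' (FDR-adjusted across methods).
#'
#' @inheritParams run_accuracy_benchmark
#' @param items_axis Axis whose vectors are the Cronbach items
#'   (`"samples"` for replicate-style consistency).
#' @return A `benchmark_report` with `consistency` records and `tests`.
#' @export
run_consistency_assessment <- function(data, methods = c("rf", "grr", "bpca", "mean"),
                                       rates = c(0.10, 0.20),
                                       mechanisms = "MIX", n_repeats = 10,
                                       seed = 1, chisq_df = 6,
                                       pct_range = c(5, 50),
                                       method_params = list(),
                                       items_axis = "samples") {
  seed <- check_seed(seed)
  complete <- prepare_complete(data)
  alpha_true <- cronbach_alpha(complete, items_axis)
  corr_true <- mean_pairwise_correlation(complete, "samples")
  grid <- tidyr::expand_grid(
    repeat_ = seq_len(n_repeats), mechanism = mechanisms, rate = rates
  )
  grid$cell_seed <- derive_seeds(seed + 1L, nrow(grid))
  out <- list(); failures <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- tryCatch({
      mask <- inject_any(complete, g$mechanism, g$rate, g$cell_seed,
                         chisq_df, pct_range)
      masked <- apply_mask(complete, mask)
      mseeds <- derive_seeds(g$cell_seed, length(methods))
      purrr::map_dfr(seq_along(methods), function(mi) {
        method <- methods[mi]
        imp <- bench_impute(masked, mask, method,
                            method_params[[method]] %||% list(), mseeds[mi])
        tibble(
          repeat_ = g$repeat_, mechanism = g$mechanism, rate = g$rate,
          method = method, seed = g$cell_seed,
          alpha_true = alpha_true,
          alpha_imputed = cronbach_alpha(imp$imputed, items_axis),
          alpha_diff = alpha_imputed - alpha_true,
          corr_true = corr_true,
          mean_pairwise_corr = mean_pairwise_correlation(imp$imputed, "samples"),
          items_axis = items_axis
        )
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- tibble(
        repeat_ = g$repeat_, mechanism = g$mechanism, rate = g$rate,
        seed = g$cell_seed, message = conditionMessage(res)
      )
    } else {
      out[[i]] <- res
    }
  }
  consistency <- dplyr::bind_rows(out)
  tests <- list()
  if (nrow(consistency) && length(methods) >= 2) {
    wil <- list()
    for (r in rates) {
      for (mech in mechanisms) {
        sub <- consistency[consistency$rate == r & consistency$mechanism == mech, ]
        if (!nrow(sub)) next
        gr <- split(sub$alpha_diff, sub$method)[methods]
        wil[[sprintf("rate_%s_%s", r, mech)]] <- pairwise_wilcoxon(gr)
      }
    }
    tt <- purrr::map_dfr(methods, function(method) {
      d <- consistency$alpha_diff[consistency$method == method]
      cbind(tibble(method = method), safe_one_sample_t(d))
    })
    tt$p_fdr <- safe_fdr(tt$p)
    tests <- list(wilcoxon_alpha_diff = wil, t_alpha_diff = tt)
  }
  new_benchmark_report(
    "consistency", consistency, consistency = consistency, tests = tests,
    provenance = list(
      experiment = "consistency", mechanisms = mechanisms, rates = rates,
      methods = methods, n_repeats = n_repeats, seed = seed,
      items_axis = items_axis,
      version = as.character(utils::packageVersion("metabomiss"))
    ),
    failures = dplyr::bind_rows(failures)
  )
}

#' Downstream regression-bias assessment
#'
#' Injects missingness into a complete table with an age covariate, imputes,
#' fits `abundance ~ covariate` per metabolite on the true and the imputed
#' data, and records coefficient and p-value differences. Per method,
#' one-sample t-tests check `beta_diff`, `abs_beta_diff`
#' (`|beta_imputed| - |beta_true|`, negative mean = coefficient shrinkage) and
#' `p_diff` for departure from zero, FDR-adjusted across methods; methods are
#' also compared pairwise by Wilcoxon rank-sum on `abs_beta_diff`.
#' Per-metabolite records carry the injected-missingness bin (default <10%,
#' 10-20%, 20-30%).
#'
#' @inheritParams run_accuracy_benchmark
#' @param covariate Per-sample covariate name (default `"age"`).
#' @return A `benchmark_report` with `regression` records and `tests`.
#' @export
run_regression_bias_assessment <- function(data, methods = c("rf", "grr", "bpca"),
                                           rates = c(0.10, 0.20),
                                           mechanisms = "MIX", n_repeats = 10,
                                           seed = 1, chisq_df = 6,
                                           pct_range = c(5, 50),
                                           method_params = list(),
                                           covariate = "age",
                                           miss_breaks = c(0, 10, 20, 30, 100)) {
  seed <- check_seed(seed)
  complete <- prepare_complete(data)
  if (is.null(covariates(complete))) {
    abort("`data` needs per-sample covariates for the regression assessment.")
  }
  grid <- tidyr::expand_grid(
    repeat_ = seq_len(n_repeats), mechanism = mechanisms, rate = rates
  )
  grid$cell_seed <- derive_seeds(seed + 2L, nrow(grid))
  out <- list(); failures <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- tryCatch({
      mask <- inject_any(complete, g$mechanism, g$rate, g$cell_seed,
                         chisq_df, pct_range)
      masked <- apply_mask(complete, mask)
      inj <- mask |>
        group_by(.data$metabolite_id) |>
        summarise(n_injected = n(), .groups = "drop") |>
        mutate(pct_missing = 100 * .data$n_injected / nrow(complete))
      mseeds <- derive_seeds(g$cell_seed, length(methods))
      purrr::map_dfr(seq_along(methods), function(mi) {
        method <- methods[mi]
        imp <- bench_impute(masked, mask, method,
                            method_params[[method]] %||% list(), mseeds[mi])
        regression_bias(complete, imp$imputed, covariate) |>
          left_join(inj, by = "metabolite_id") |>
          mutate(
            pct_missing = dplyr::coalesce(.data$pct_missing, 0),
            missingness_bin = bin_label(.data$pct_missing, miss_breaks),
            repeat_ = g$repeat_, mechanism = g$mechanism, rate = g$rate,
            method = method, seed = g$cell_seed
          )
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- tibble(
        repeat_ = g$repeat_, mechanism = g$mechanism, rate = g$rate,
        seed = g$cell_seed, message = conditionMessage(res)
      )
    } else {
      out[[i]] <- res
    }
  }
  regression <- dplyr::bind_rows(out)
  tests <- list()
  if (nrow(regression)) {
    tfam <- function(col) {
      tt <- purrr::map_dfr(methods, function(method) {
        d <- regression[[col]][regression$method == method]
        cbind(tibble(method = method), safe_one_sample_t(d))
      })
      tt$p_fdr <- safe_fdr(tt$p)
      tt
    }
    gr <- split(regression$abs_beta_diff, regression$method)[methods]
    tests <- list(
      t_beta_diff = tfam("beta_diff"),
      t_abs_beta_diff = tfam("abs_beta_diff"),
      t_p_diff = tfam("p_diff"),
      wilcoxon_abs_beta_diff = if (length(methods) >= 2) pairwise_wilcoxon(gr)
    )
  }
  new_benchmark_report(
    "regression_bias", regression, regression = regression, tests = tests,
    provenance = list(
      experiment = "regression_bias", mechanisms = mechanisms, rates = rates,
      methods = methods, n_repeats = n_repeats, seed = seed,
      covariate = covariate,
      version = as.character(utils::packageVersion("metabomiss"))
    ),
    failures = dplyr::bind_rows(failures)
  )
}

#' In-depth single-value imputation evaluation
#'
#' The deep-dive protocol for one method (random forest by default) on a
#' *full* table with natural missingness: metabolites above `max_pct` percent
#' missing are dropped, then `n_iter` single observed cells are masked one at
#' a time (without replacement), the whole table is imputed, and only the
#' error at the inserted cell is recorded together with its host metabolite's
#' percent missingness and CV. Percent bias is computed on the raw abundance
#' scale. Optionally, a sweep over wider overall missingness rates re-runs
#' the Cronbach-alpha and regression-difference assessments on the complete
#' part of the table.
#'
#' @inheritParams run_accuracy_benchmark
#' @param n_iter Number of single-cell insertions (capped at the number of
#'   eligible cells, with a warning).
#' @param method Imputation method for the deep dive.
#' @param max_pct Pre-filter: drop metabolites with more than this percent
#'   missing.
#' @param pb_breaks Bin edges (percent metabolite missingness) for the
#'   percent-bias summary.
#' @param sweep_rates Overall missingness rates for the alpha/regression
#'   sweep, or `NULL` to skip it.
#' @param sweep_repeats Repeats per sweep rate.
#' @param covariate Covariate for the sweep regressions (skipped if absent).
#' @return A `benchmark_report`; `records` has one row per insertion,
#'   `summary` the binned percent-bias medians, and `consistency`/`regression`
#'   the sweep records.
#' @export
run_indepth_single_value <- function(data, n_iter = 200, seed = 1,
                                     method = "rf", method_params = list(),
                                     max_pct = 75,
                                     pb_breaks = c(0, 10, 20, 30, 45, 100),
                                     sweep_rates = seq(0.1, 0.7, by = 0.1),
                                     sweep_repeats = 3, chisq_df = 6,
                                     pct_range = c(5, 50),
                                     covariate = "age") {
  seed <- check_seed(seed)
  if (table_scale(data) == "raw") data <- log10_transform(data)
  full <- filter_by_missingness(data, max_pct)
  m <- as_abund_matrix(full)
  n_eligible <- sum(!is.na(m))
  if (n_iter > n_eligible) {
    warn(sprintf("n_iter capped at the %d eligible observed cells.", n_eligible))
    n_iter <- n_eligible
  }
  ctx <- summarize_metabolites(full)
  seeds <- derive_seeds(seed + 3L, n_iter)
  used <- tibble(sample_id = character(0), metabolite_id = character(0))
  recs <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    ins <- insert_single_missing(full, seeds[i], exclude = used)
    used <- dplyr::bind_rows(
      used, ins$position[, c("sample_id", "metabolite_id")]
    )
    masked <- apply_mask(full, ins$mask)
    imp <- bench_impute(masked, ins$mask, method, method_params, seeds[i])
    got <- as_abund_matrix(imp$imputed)[
      cbind(match(ins$position$sample_id, rownames(m)),
            match(ins$position$metabolite_id, colnames(m)))
    ]
    truth_raw <- 10^ins$position$true_value
    recs[[i]] <- mutate(
      ins$position,
      iteration = i, seed = seeds[i], method = method,
      imputed_value = got,
      abs_diff = abs(got - .data$true_value),
      percent_bias = 100 * abs(10^got - truth_raw) / truth_raw
    )
  }
  records <- dplyr::bind_rows(recs) |>
    mutate(missingness_bin = bin_label(.data$pct_missing, pb_breaks))
  summary <- records |>
    group_by(.data$missingness_bin) |>
    summarise(
      n = n(),
      median_pb = stats::median(.data$percent_bias),
      median_abs_diff = stats::median(.data$abs_diff),
      .groups = "drop"
    )
  consistency <- tibble(); regression <- tibble()
  if (!is.null(sweep_rates)) {
    complete <- split_complete(full)$complete
    has_cov <- !is.null(covariates(complete)) &&
      covariate %in% names(covariates(complete))
    alpha_true <- cronbach_alpha(complete, "metabolites")
    sg <- tidyr::expand_grid(repeat_ = seq_len(sweep_repeats),
                             rate = sweep_rates)
    sg$cell_seed <- derive_seeds(seed + 4L, nrow(sg))
    cons <- list(); regs <- list()
    for (i in seq_len(nrow(sg))) {
      g <- sg[i, ]
      res <- tryCatch({
        mask <- inject_mixture(complete, g$rate, g$cell_seed,
                               chisq_df = chisq_df, pct_range = pct_range)
        masked <- apply_mask(complete, mask)
        imp <- bench_impute(masked, mask, method, method_params, g$cell_seed)
        ali <- cronbach_alpha(imp$imputed, "metabolites")
        cons[[i]] <- tibble(
          repeat_ = g$repeat_, rate = g$rate, method = method,
          seed = g$cell_seed, alpha_true = alpha_true, alpha_imputed = ali,
          alpha_diff = ali - alpha_true, items_axis = "metabolites"
        )
        if (has_cov) {
          regs[[i]] <- regression_bias(complete, imp$imputed, covariate) |>
            mutate(repeat_ = g$repeat_, rate = g$rate, method = method,
                   seed = g$cell_seed)
        }
        NULL
      }, error = function(e) e)
    }
    consistency <- dplyr::bind_rows(cons)
    regression <- dplyr::bind_rows(regs)
  }
  new_benchmark_report(
    "indepth_single_value", records, summary = summary,
    consistency = consistency, regression = regression,
    provenance = list(
      experiment = "indepth_single_value", n_iter = n_iter, seed = seed,
      method = method, max_pct = max_pct, sweep_rates = sweep_rates,
      sweep_repeats = sweep_repeats,
      version = as.character(utils::packageVersion("metabomiss"))
    )
  )
}
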