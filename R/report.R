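#' Write a benchmark report to disk
#'
#' Writes tidy CSVs (`records.csv`, `per_metabolite.csv`, `consistency.csv`,
#' `regression.csv`, `summary.csv`), the statistical tests as `tests.json`,
#' and the provenance block as `provenance.json`. Empty sections become
#' header-only files, never absent files, so downstream tooling can rely on
#' the contract. With `figures = TRUE` a boxplot figure per report type is
#' written as PDF.
#'
#' @param report A `benchmark_report`.
#' @param output_dir Directory (created if needed).
#' @param figures Also write an [autoplot.benchmark_report()] figure.
#' @return The vector of written paths, invisibly.
#' @export
write_report <- function(report, output_dir, figures = FALSE) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) abort("Could not create `output_dir`.")
  paths <- character(0)
  sections <- list(
    records = report$records, per_metabolite = report$per_metabolite,
    consistency = report$consistency, regression = report$regression,
    summary = report$summary
  )
  for (nm in names(sections)) {
    p <- file.path(output_dir, paste0(nm, ".csv"))
    sec <- as_tibble(sections[[nm]])
    if (ncol(sec)) sec <- mutate(sec, dplyr::across(
      dplyr::where(is.factor), as.character
    ))
    readr::write_csv(sec, p, na = "NA", progress = FALSE)
    paths <- c(paths, p)
  }
  tests_path <- file.path(output_dir, "tests.json")
  jsonlite::write_json(report$tests, tests_path, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  prov_path <- file.path(output_dir, "provenance.json")
  jsonlite::write_json(report$provenance, prov_path, digits = NA,
                       pretty = TRUE, auto_unbox = TRUE, na = "null")
  paths <- c(paths, tests_path, prov_path)
  if (figures) {
    fig_path <- file.path(output_dir, "report.pdf")
    grDevices::pdf(fig_path, width = 7, height = 5)
    print(autoplot(report))
    grDevices::dev.off()
    paths <- c(paths, fig_path)
  }
  invisible(paths)
}

#' Tidy a benchmark report
#'
#' @param x A `benchmark_report`.
#' @param section Which section to return: `"records"` (default),
#'   `"per_metabolite"`, `"consistency"`, `"regression"` or `"summary"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, section = "records", ...) {
  section <- match.arg(section, c("records", "per_metabolite", "consistency",
                                  "regression", "summary"))
  as_tibble(x[[section]])
}

#' One-line summary of a benchmark report
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return A one-row tibble: experiment, record count, number of methods,
#'   number of failed cells, master seed.
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  tibble(
    experiment = x$experiment,
    n_records = nrow(x$records),
    n_methods = length(unique(x$records$method %||% character(0))),
    n_failures = nrow(x$failures %||% tibble()),
    seed = x$provenance$seed %||% NA_integer_
  )
}

#' Boxplot view of a benchmark report
#'
#' Accuracy reports show masked-cell RMSE by method; consistency reports show
#' the Cronbach-alpha difference by method (zero line = no bias); regression
#' reports show the coefficient-magnitude difference by method; in-depth
#' reports show percent bias by host-metabolite missingness bin.
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  r <- object$records
  switch(object$experiment,
    accuracy = ggplot2::ggplot(r, ggplot2::aes(
      x = stats::reorder(.data$method, .data$rmse, stats::median),
      y = .data$rmse
    )) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::labs(x = NULL, y = "RMSE (log10 scale, masked cells)",
                    title = "Imputation accuracy by method"),
    consistency = ggplot2::ggplot(r, ggplot2::aes(
      x = .data$method, y = .data$alpha_diff
    )) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::facet_wrap(~rate, labeller = ggplot2::label_both) +
      ggplot2::labs(x = NULL, y = "Cronbach's alpha (imputed - true)",
                    title = "Internal-consistency bias by method"),
    regression_bias = ggplot2::ggplot(r, ggplot2::aes(
      x = .data$method, y = .data$abs_beta_diff
    )) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::facet_wrap(~missingness_bin) +
      ggplot2::labs(x = NULL, y = "|beta| imputed - |beta| true",
                    title = "Regression-coefficient shrinkage by method"),
    indepth_single_value = ggplot2::ggplot(r, ggplot2::aes(
      x = .data$missingness_bin, y = .data$percent_bias
    )) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::labs(x = "Host-metabolite missingness (%)",
                    y = "Percent bias (raw scale)",
                    title = "Single-value imputation accuracy vs missingness"),
    abort(sprintf("No plot defined for experiment '%s'.", object$experiment))
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
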