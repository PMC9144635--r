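#' Impute a table with any of the ten registered methods
#'
#' One uniform entry point over the ten single-imputation methods. `params`
#' overrides the registered defaults (see [imputation_methods()]); unknown
#' methods or parameters error before any computation. Every imputer
#' guarantees that originally observed cells are returned bit-identical and
#' that the result contains no missing entries.
#'
#' Model-based methods (kNN, SVD, BPCA, LLS, RF, GRR, QR) are intended to run
#' on the log10 analysis scale; `zero` and `hm` have explicit semantics on
#' both scales.
#'
#' @param table An [abundance_table()] with (or without) missing entries.
#' @param method One of `"zero"`, `"hm"`, `"mean"`, `"knn"`, `"svd"`,
#'   `"bpca"`, `"lls"`, `"rf"`, `"grr"`, `"qr"`.
#' @param params Named list of method parameters overriding the defaults.
#' @param seed Integer seed forwarded to stochastic methods.
#' @return An `imputation_result`: a list with `imputed` (completed table),
#'   `method`, `params`, `n_iterations`, `converged`, `seed` and
#'   `diagnostics` (e.g. recorded fallbacks).
#' @examples
#' tb <- abundance_table(matrix(c(1, 2, NA, 4, 5, 6), 3, 2,
#'   dimnames = list(paste0("s", 1:3), c("a", "b"))
#' ))
#' impute(tb, "mean")$imputed
#' @export
impute <- function(table, method, params = list(), seed = 1) {
  registry <- imputation_methods()
  if (!is.character(method) || length(method) != 1 || !method %in% registry$method) {
    abort(sprintf("Unknown imputation method: %s",
                  paste(utils::head(method, 3), collapse = ", ")))
  }
  defaults <- registry$defaults[[match(method, registry$method)]]
  extra <- setdiff(names(params), names(defaults))
  if (length(extra)) {
    abort(sprintf("Unknown parameter(s) for method '%s': %s",
                  method, paste(extra, collapse = ", ")))
  }
  pars <- utils::modifyList(defaults, params)
  fn <- get(paste0("impute_", method), mode = "function")
  uses_seed <- "seed" %in% names(formals(fn))
  args <- c(list(table), pars, if (uses_seed) list(seed = seed))
  do.call(fn, args)
}

#' The imputation-method registry
#'
#' @return A tibble with one row per method: its name and the default
#'   parameters the dispatcher applies.
#' @export
imputation_methods <- function() {
  tibble(
    method = c("zero", "hm", "mean", "knn", "svd", "bpca", "lls", "rf",
               "grr", "qr"),
    defaults = list(
      list(),
      list(),
      list(),
      list(k = 10, weighted = TRUE),
      list(rank = 5, max_iter = 100, tol = 1e-5),
      list(n_components = NULL, max_iter = 200, tol = 1e-5),
      list(k = 10),
      list(n_trees = 100, max_iter = 10),
      list(lambda_grid = 10^seq(-4, 2, length.out = 25), max_iter = 10,
           tol = 1e-4, n_folds = 5),
      list(quantile = 0.5, max_iter = 5)
    )
  )
}

new_imputation_result <- function(table, filled, method, params = list(),
                                  n_iterations = 0L, converged = TRUE,
                                  seed = NA_integer_, diagnostics = list()) {
  orig <- as_abund_matrix(table)
  miss <- is.na(orig)
  # observed cells are restored verbatim: imputers never touch observed data
  filled[!miss] <- orig[!miss]
  if (anyNA(filled)) abort("Internal error: imputation left missing cells.")
  structure(
    list(
      imputed = abund_from_matrix(filled, table),
      method = method, params = params,
      n_iterations = as.integer(n_iterations), converged = converged,
      seed = seed, diagnostics = diagnostics,
      mask = miss
    ),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf(
    "# Imputation result: method '%s', %d cells imputed, %d iterations, %s\n",
    x$method, sum(x$mask), x$n_iterations,
    if (isTRUE(x$converged)) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Tidy an imputation result into one row per imputed cell
#'
#' @param x An `imputation_result`.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `metabolite_id`, `imputed_value`.
#' @method tidy imputation_result
#' @export
tidy.imputation_result <- function(x, ...) {
  m <- as_abund_matrix(x$imputed)
  idx <- which(x$mask)
  tibble(
    sample_id = rownames(m)[(idx - 1L) %% nrow(m) + 1L],
    metabolite_id = colnames(m)[(idx - 1L) %/% nrow(m) + 1L],
    imputed_value = m[idx]
  )
}

#' One-line summary of an imputation result
#'
#' @inheritParams tidy.imputation_result
#' @return A one-row tibble: method, cells imputed, iterations, convergence,
#'   number of recorded fallbacks.
#' @method glance imputation_result
#' @export
glance.imputation_result <- function(x, ...) {
  tibble(
    method = x$method, n_imputed = sum(x$mask),
    n_iterations = x$n_iterations, converged = isTRUE(x$converged),
    n_fallbacks = length(x$diagnostics$fallbacks %||% character(0))
  )
}

# shared entry: matrix + missing pattern, with optional per-column checks
impute_setup <- function(table, require_observed = TRUE) {
  validate_abund_tbl(table)
  m <- as_abund_matrix(table)
  if (require_observed && any(colSums(!is.na(m)) == 0)) {
    bad <- colnames(m)[colSums(!is.na(m)) == 0]
    abort(sprintf("Metabolite(s) with no observed values: %s",
                  paste(bad, collapse = ", ")))
  }
  m
}

col_mean_fill <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  miss <- which(is.na(m), arr.ind = TRUE)
  m[miss] <- mu[miss[, 2]]
  m
}

#' Zero imputation
#'
#' Missing cells become 0 on the table's current scale (a determined-value
#' substitution; on the log10 scale 0 corresponds to a raw abundance of 1).
#'
#' @inheritParams impute
#' @return An `imputation_result`.
#' @export
impute_zero <- function(table) {
  m <- impute_setup(table, require_observed = FALSE)
  m[is.na(m)] <- 0
  new_imputation_result(table, m, "zero")
}

#' Half-minimum imputation
#'
#' A limit-of-detection surrogate: missing cells become half the metabolite's
#' minimum observed value on the raw scale, or equivalently
#' `min - log10(2)` on the log10 scale.
#'
#' @inheritParams impute
#' @return An `imputation_result`.
#' @export
impute_hm <- function(table) {
  m <- impute_setup(table)
  mins <- apply(m, 2, min, na.rm = TRUE)
  fill <- if (table_scale(table) == "log10") mins - log10(2) else mins / 2
  miss <- which(is.na(m), arr.ind = TRUE)
  m[miss] <- fill[miss[, 2]]
  new_imputation_result(table, m, "hm")
}

#' Mean imputation
#'
#' Missing cells become the metabolite's observed mean.
#'
#' @inheritParams impute
#' @return An `imputation_result`.
#' @export
impute_mean <- function(table) {
  m <- impute_setup(table)
  new_imputation_result(table, col_mean_fill(m), "mean")
}
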