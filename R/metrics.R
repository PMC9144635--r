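#' Imputation accuracy over masked cells
#'
#' `rmse()` is the root-mean-squared error and `percent_bias()` the mean
#' absolute relative deviation (in percent) between imputed and true values,
#' computed *only* over the cells of `mask`; cells outside the mask never
#' influence either metric. Both are conventionally evaluated on the log10
#' analysis scale (the scale imputation runs on); pass raw-scale tables for
#' raw-scale percent bias.
#'
#' @param truth The source [abundance_table()] (complete over the mask).
#' @param imputed The completed table (e.g. `result$imputed`).
#' @param mask A missingness mask aligned to both tables.
#' @param na_zero_truth For `percent_bias()`: `"error"` (default) rejects a
#'   masked cell with zero truth; `"drop"` excludes such cells.
#' @return A single non-negative number.
#' @examples
#' # truth (1, 2) imputed as (2, 4): rmse = sqrt((1 + 4) / 2)
#' @export
rmse <- function(truth, imputed, mask) {
  v <- masked_values(truth, imputed, mask)
  sqrt(mean((v$imputed - v$truth)^2))
}

#' @rdname rmse
#' @export
percent_bias <- function(truth, imputed, mask,
                         na_zero_truth = c("error", "drop")) {
  na_zero_truth <- match.arg(na_zero_truth)
  v <- masked_values(truth, imputed, mask)
  zero <- v$truth == 0
  if (any(zero)) {
    if (na_zero_truth == "error") {
      abort("Masked cell with zero true value; percent bias undefined.")
    }
    v <- v[!zero, ]
    if (!nrow(v)) abort("No masked cells with nonzero truth remain.")
  }
  mean(100 * abs(v$imputed - v$truth) / abs(v$truth))
}

masked_values <- function(truth, imputed, mask) {
  if (nrow(mask) == 0) abort("`mask` is empty.")
  mt <- as_abund_matrix(truth)
  mi <- as_abund_matrix(imputed)
  if (!identical(dim(mt), dim(mi))) abort("Table shapes differ.")
  idx <- mask_indices(mt, mask)
  tibble(truth = mt[idx], imputed = mi[idx],
         metabolite_id = mask$metabolite_id)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(item sums))`, with
#' items along the requested axis. For technical-replicate consistency the
#' items are the samples; for metabolite-correlation analyses the items are
#' the metabolites. The axis is always explicit, never inferred. Alpha is at
#' most 1 and can be negative for pathological covariance structures.
#'
#' @param table A complete [abundance_table()].
#' @param items_axis `"samples"` or `"metabolites"`.
#' @return A single number `<= 1`.
#' @export
cronbach_alpha <- function(table, items_axis = c("samples", "metabolites")) {
  items_axis <- match.arg(items_axis)
  m <- as_abund_matrix(table)
  if (anyNA(m)) abort("Cronbach's alpha requires a complete table.")
  items <- if (items_axis == "samples") t(m) else m # observations x items
  k <- ncol(items)
  if (k < 2) abort("Need at least 2 items.")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) abort("Zero total variance; alpha undefined.")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Mean pairwise Pearson correlation
#'
#' Mean of the Pearson correlations over all unordered pairs of vectors along
#' the chosen axis (e.g. sample-to-sample correlation of technical
#' replicates). Constant vectors have undefined correlations; their pairs are
#' excluded with a warning.
#'
#' @param table A complete [abundance_table()].
#' @param axis `"samples"` or `"metabolites"`.
#' @return A number in `[-1, 1]`.
#' @export
mean_pairwise_correlation <- function(table, axis = c("samples", "metabolites")) {
  axis <- match.arg(axis)
  m <- as_abund_matrix(table)
  if (anyNA(m)) abort("Mean pairwise correlation requires a complete table.")
  vecs <- if (axis == "samples") t(m) else m
  if (ncol(vecs) < 2) abort("Need at least 2 vectors.")
  const <- apply(vecs, 2, stats::sd) == 0
  if (any(const)) {
    warn(sprintf("Excluding %d constant vector(s) from correlation pairs.",
                 sum(const)))
    vecs <- vecs[, !const, drop = FALSE]
    if (ncol(vecs) < 2) abort("Fewer than 2 non-constant vectors remain.")
  }
  cc <- stats::cor(vecs)
  mean(cc[upper.tri(cc)])
}

#' Per-metabolite regression bias after imputation
#'
#' Fits, for every metabolite, the simple linear regression
#' `abundance ~ covariate` (covariate as predictor, metabolite abundance as
#' outcome) on both the true and the imputed table, and records the slopes,
#' their two-sided p-values, and the differences. `p_diff` is
#' `p_imputed - p_true`, so a positive mean reads "p-values less significant
#' after imputation"; `beta_diff` is `beta_imputed - beta_true`.
#'
#' @param truth_table,imputed_table Complete [abundance_table()]s with the
#'   same layout.
#' @param covariate Name of the per-sample covariate to regress on
#'   (default `"age"`).
#' @return A tibble with one row per metabolite: `metabolite_id`,
#'   `beta_true`, `beta_imputed`, `beta_diff`, `abs_beta_diff`
#'   (`|beta_imputed| - |beta_true|`, negative = shrinkage), `p_true`,
#'   `p_imputed`, `p_diff`.
#' @export
regression_bias <- function(truth_table, imputed_table, covariate = "age") {
  mt <- as_abund_matrix(truth_table)
  mi <- as_abund_matrix(imputed_table)
  if (!identical(dim(mt), dim(mi))) abort("Table shapes differ.")
  if (anyNA(mt) || anyNA(mi)) abort("Both tables must be complete.")
  if (nrow(mt) < 3) abort("Need at least 3 samples for regression.")
  cov <- covariates(truth_table)
  if (is.null(cov) || !covariate %in% names(cov)) {
    abort(sprintf("Covariate `%s` not found on `truth_table`.", covariate))
  }
  x <- cov[[covariate]][match(rownames(mt), cov$sample_id)]
  if (anyNA(x)) abort("Covariate missing for some samples.")
  ft <- fast_ols(x, mt)
  fi <- fast_ols(x, mi)
  tibble(
    metabolite_id = colnames(mt),
    beta_true = ft$beta, beta_imputed = fi$beta,
    beta_diff = fi$beta - ft$beta,
    abs_beta_diff = abs(fi$beta) - abs(ft$beta),
    p_true = ft$p, p_imputed = fi$p,
    p_diff = fi$p - ft$p
  )
}

# simultaneous simple OLS of every column of Y on x, with two-sided slope p
fast_ols <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) abort("Constant covariate; regression undefined.")
  beta <- as.numeric(crossprod(xc, sweep(Y, 2, colMeans(Y))) / sxx)
  fitted <- outer(x, beta) + rep(colMeans(Y) - beta * mean(x), each = n)
  rss <- colSums((Y - fitted)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- ifelse(se > 0, beta / se, Inf * sign(beta))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(beta = beta, p = unname(p))
}
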