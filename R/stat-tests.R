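#' One-sample t-test for departure from a reference value
#'
#' Classical two-sided one-sample t-test, used on the per-metabolite
#' differences between imputed and true regression coefficients (or p-values,
#' or Cronbach's alphas) to test for systematic bias.
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @param mu0 Null value (default 0).
#' @return A tibble with `estimate` (mean), `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("Need at least 2 values.")
  if (stats::sd(values) == 0) abort("Zero standard deviation; t undefined.")
  ht <- stats::t.test(values, mu = mu0)
  tibble(
    estimate = unname(ht$estimate), t = unname(ht$statistic),
    df = unname(ht$parameter), p = ht$p.value
  )
}

#' Pairwise Wilcoxon rank-sum tests
#'
#' Two-sided unpaired Wilcoxon (Mann-Whitney) rank-sum p-value for every
#' unordered pair of groups — the standard method-vs-method comparison for
#' error or bias distributions. Small, tie-free groups get the exact null;
#' otherwise a normal approximation with tie correction is used.
#'
#' @param groups Named list of numeric vectors (each non-empty).
#' @return A symmetric matrix of p-values with `NA` on the diagonal.
#' @export
pairwise_wilcoxon <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least 2 numeric vectors.")
  }
  if (any(!lengths(groups))) abort("Empty group.")
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      pv <- suppressWarnings(
        stats::wilcox.test(groups[[a]], groups[[b]], exact = NULL,
                           correct = TRUE)$p.value
      )
      p[a, b] <- p[b, a] <- pv
    }
  }
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values; adjusted
#' values are monotone in the order statistics and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  stats::p.adjust(pvalues, method = "BH")
}
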