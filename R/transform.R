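#' Log10-transform a raw abundance table
#'
#' Peak tables are analyzed on the log10 scale; this converts a raw-scale
#' table, leaving missing entries missing. All observed raw values must be
#' strictly positive.
#'
#' @param table A raw-scale [abundance_table()].
#' @return The same table on the log10 scale.
#' @examples
#' tb <- abundance_table(matrix(c(100, 1), 1,
#'   dimnames = list("s1", c("a", "b"))
#' ))
#' log10_transform(tb) # 2.0 and 0.0
#' @export
log10_transform <- function(table) {
  validate_abund_tbl(table)
  if (table_scale(table) != "raw") {
    abort("`table` is already on the log10 scale.")
  }
  m <- as_abund_matrix(table)
  if (any(m <= 0, na.rm = TRUE)) {
    abort("log10 transform requires strictly positive observed abundances.")
  }
  abund_from_matrix(log10(m), table, scale = "log10")
}

#' Per-metabolite summary statistics
#'
#' Mean, sample (n-1) standard deviation, coefficient of variation and percent
#' missingness for every metabolite. The CV is always the conventional
#' analytical CV on the raw abundance scale: for a log10-scale table the
#' values are back-transformed (`10^x`) first. A CV is flagged undefined
#' (`cv_defined = FALSE`, `cv = NA`) when fewer than 2 values are observed or
#' the raw mean is not positive — never silently reported as zero.
#'
#' @param table An [abundance_table()].
#' @return A tibble with one row per metabolite: `metabolite_id`, `mean`,
#'   `sd`, `cv`, `cv_defined`, `pct_missing` (0-100). `mean` and `sd` are on
#'   the table's own scale; `cv` is raw-scale.
#' @export
summarize_metabolites <- function(table) {
  validate_abund_tbl(table)
  m <- as_abund_matrix(table)
  raw <- if (table_scale(table) == "log10") 10^m else m
  per <- function(j) {
    x <- m[, j]
    obs <- x[!is.na(x)]
    rx <- raw[, j]
    robs <- rx[!is.na(rx)]
    cv_ok <- length(robs) >= 2 && mean(robs) > 0
    tibble(
      metabolite_id = colnames(m)[j],
      mean = if (length(obs)) mean(obs) else NA_real_,
      sd = if (length(obs) >= 2) stats::sd(obs) else NA_real_,
      cv = if (cv_ok) stats::sd(robs) / mean(robs) else NA_real_,
      cv_defined = cv_ok,
      pct_missing = 100 * mean(is.na(x))
    )
  }
  purrr::map_dfr(seq_len(ncol(m)), per)
}

#' Split a table into complete and full parts
#'
#' Mirrors the standard pre-processing split: the *complete* table keeps
#' exactly the metabolites with zero missing entries (used for controlled
#' missingness injection), the *full* table is the unmodified input.
#'
#' @param table An [abundance_table()].
#' @return A list with elements `complete` and `full`.
#' @export
split_complete <- function(table) {
  validate_abund_tbl(table)
  m <- as_abund_matrix(table)
  keep <- colnames(m)[colSums(is.na(m)) == 0]
  comp <- new_abund_tbl(
    as_tibble(table)[, c("sample_id", keep), drop = FALSE],
    scale = table_scale(table), covariates = covariates(table)
  )
  list(complete = comp, full = table)
}
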