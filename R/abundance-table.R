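#' Abundance tables
#'
#' The package's universal currency is the *abundance table*: a tibble with a
#' `sample_id` character column followed by one numeric column per metabolite
#' (rows are samples). Two attributes travel with it:
#'
#' * `scale` — `"raw"` (peak heights, strictly positive where observed) or
#'   `"log10"`;
#' * `covariates` — an optional per-sample tibble (keyed by `sample_id`) with
#'   columns such as `age` (years), `sex`, `batch`.
#'
#' Missing peaks are `NA`. A value of 0 on the raw scale is treated as an
#' upstream processing error, not as missingness, and is rejected.
#'
#' @param x A data frame with a `sample_id` column and numeric metabolite
#'   columns, or a numeric matrix with sample IDs as row names.
#' @param scale `"raw"` or `"log10"`.
#' @param covariates Optional per-sample data frame keyed by `sample_id`.
#' @return An `abund_tbl`, a tibble subclass.
#' @examples
#' m <- matrix(c(10, 20, NA, 40), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("ala", "gly"))
#' )
#' abundance_table(m)
#' @export
abundance_table <- function(x, scale = c("raw", "log10"), covariates = NULL) {
  scale <- match.arg(scale)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      rownames(x) <- sprintf("sample_%03d", seq_len(nrow(x)))
    }
    if (is.null(colnames(x))) {
      colnames(x) <- sprintf("met_%03d", seq_len(ncol(x)))
    }
    x <- dplyr::bind_cols(
      tibble(sample_id = rownames(x)),
      as_tibble(x, .name_repair = "minimal")
    )
  }
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("An abundance table needs a `sample_id` column.")
  }
  x$sample_id <- as.character(x$sample_id)
  x <- dplyr::relocate(x, "sample_id")
  out <- new_abund_tbl(x, scale = scale, covariates = covariates)
  validate_abund_tbl(out)
}

new_abund_tbl <- function(x, scale, covariates = NULL) {
  if (!is.null(covariates)) covariates <- as_tibble(covariates)
  structure(
    x,
    scale = scale,
    covariates = covariates,
    class = c("abund_tbl", class(as_tibble(x)))
  )
}

validate_abund_tbl <- function(x) {
  ids <- x$sample_id
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicated sample IDs: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  mets <- setdiff(names(x), "sample_id")
  if (anyDuplicated(mets)) {
    abort(sprintf("Duplicated metabolite IDs: %s",
                  paste(unique(mets[duplicated(mets)]), collapse = ", ")))
  }
  for (m in mets) {
    if (!is.numeric(x[[m]])) {
      abort(sprintf("Metabolite column `%s` is not numeric.", m))
    }
  }
  if (identical(attr(x, "scale"), "raw") && length(mets)) {
    v <- as_abund_matrix(x)
    if (any(v <= 0, na.rm = TRUE)) {
      abort("Raw-scale abundances must be strictly positive where observed.")
    }
  }
  cov <- attr(x, "covariates")
  if (!is.null(cov)) {
    if (!"sample_id" %in% names(cov)) {
      abort("`covariates` needs a `sample_id` column.")
    }
    if (!setequal(cov$sample_id, ids) || anyDuplicated(cov$sample_id)) {
      abort("`covariates` must have exactly one row per sample.")
    }
  }
  x
}

#' @export
print.abund_tbl <- function(x, ...) {
  n_met <- ncol(x) - 1L
  n_miss <- sum(is.na(as_abund_matrix(x)))
  cat(sprintf(
    "# Abundance table: %d samples x %d metabolites (%s scale, %d missing)\n",
    nrow(x), n_met, table_scale(x), n_miss
  ))
  if (!is.null(covariates(x))) {
    cat(sprintf("# Covariates: %s\n",
                paste(setdiff(names(covariates(x)), "sample_id"), collapse = ", ")))
  }
  NextMethod()
}

#' Accessors for abundance-table metadata
#'
#' @param x An `abund_tbl`.
#' @return `table_scale()` returns `"raw"` or `"log10"`; `covariates()` the
#'   per-sample covariate tibble or `NULL`; `metabolite_ids()` a character
#'   vector; `as_abund_matrix()` the numeric samples-by-metabolites matrix with
#'   sample IDs as row names.
#' @export
table_scale <- function(x) attr(x, "scale") %||% "raw"

#' @rdname table_scale
#' @export
covariates <- function(x) attr(x, "covariates")

#' @rdname table_scale
#' @export
metabolite_ids <- function(x) setdiff(names(x), "sample_id")

#' @rdname table_scale
#' @export
as_abund_matrix <- function(x) {
  mets <- metabolite_ids(x)
  m <- as.matrix(as_tibble(x)[, mets, drop = FALSE])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

# rebuild an abund_tbl from a matrix, inheriting metadata from a template
abund_from_matrix <- function(m, template, scale = table_scale(template)) {
  tb <- dplyr::bind_cols(
    tibble(sample_id = rownames(m) %||% template$sample_id),
    as_tibble(m, .name_repair = "minimal")
  )
  new_abund_tbl(tb, scale = scale, covariates = covariates(template))
}
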