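#' Read a wide-format abundance table
#'
#' Reads a delimited samples-by-metabolites (or transposed) peak table.
#' Cells matching a sentinel string become missing; any other non-numeric cell
#' is an error that names the offending row and column.
#'
#' @param path Path to a CSV (or TSV, by extension) file. The first column
#'   holds IDs for whatever `orientation` says the rows are.
#' @param orientation `"samples"` if rows are samples (the default dialect) or
#'   `"metabolites"` if rows are metabolites.
#' @param sentinels Strings parsed as missing. `"0"` is deliberately not a
#'   default sentinel: zeros on the raw scale are a scale error, not
#'   missingness.
#' @param scale Scale flag to attach, `"raw"` or `"log10"`.
#' @param covariates_path Optional CSV of per-sample covariates keyed by
#'   `sample_id`.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, orientation = c("samples", "metabolites"),
                           sentinels = c("", "NA", "NaN"),
                           scale = c("raw", "log10"),
                           covariates_path = NULL) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), name_repair = "minimal", progress = FALSE
  )
  if (ncol(raw) < 1) abort("Empty table.")
  id_col <- names(raw)[1]
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicated row IDs in `%s`: %s", id_col,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(names(raw)[-1])) {
    dup <- names(raw)[-1]
    abort(sprintf("Duplicated column names: %s",
                  paste(unique(dup[duplicated(dup)]), collapse = ", ")))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  is_sent <- matrix(vals %in% sentinels | is.na(vals), nrow(vals))
  parse_ok <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- !is_sent & is.na(parse_ok)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-numeric cell \"%s\" at row '%s', column '%s' (not in the sentinel set).",
      vals[idx[1], idx[2]], ids[idx[1]], colnames(vals)[idx[2]]
    ))
  }
  num[!is_sent] <- parse_ok[!is_sent]
  rownames(num) <- ids
  if (orientation == "metabolites") num <- t(num)
  cov <- if (!is.null(covariates_path)) {
    readr::read_csv(covariates_path, show_col_types = FALSE, progress = FALSE)
  }
  abundance_table(num, scale = scale, covariates = cov)
}

#' Write an abundance table to CSV
#'
#' Deterministic output: columns in table order, missing cells written as
#' `"NA"`, full-precision doubles so that a read/write round trip is lossless.
#'
#' @param table An [abundance_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path) {
  validate_abund_tbl(table)
  readr::write_csv(as_tibble(table), path, na = "NA", progress = FALSE)
  invisible(path)
}
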