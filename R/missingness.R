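#' Missingness masks
#'
#' Injectors return a *missingness mask*: a long tibble with one row per
#' injected cell (`sample_id`, `metabolite_id`, `mechanism`, `true_value`,
#' `event`) plus bookkeeping attributes `target_rate`, `realized_rate`
#' (injected cells over originally observed cells), `seed`, `n_observed` and,
#' for MAR, the per-event `(driver, target)` provenance in `events`. Injected
#' cells are always drawn from cells observed in the source table; already
#' missing cells are never re-masked.
#'
#' @param table A (typically complete) [abundance_table()].
#' @param rate Target global missingness rate in `[0, 1)`, as a fraction of
#'   originally observed cells. Cell counts use round-half-away-from-zero.
#' @param seed Integer seed.
#' @name missingness_mask
NULL

new_miss_mask <- function(cells, table, target_rate, seed, events = NULL) {
  n_obs <- sum(!is.na(as_abund_matrix(table)))
  out <- structure(
    as_tibble(cells),
    target_rate = target_rate,
    realized_rate = nrow(cells) / n_obs,
    n_observed = n_obs,
    seed = seed,
    events = events,
    class = c("miss_mask", class(tibble()))
  )
  out
}

#' @export
print.miss_mask <- function(x, ...) {
  cat(sprintf(
    "# Missingness mask: %d cells (target rate %.4g, realized %.4g, seed %d)\n",
    nrow(x), attr(x, "target_rate"), attr(x, "realized_rate"), attr(x, "seed")
  ))
  NextMethod()
}

#' @rdname table_scale
#' @export
realized_rate <- function(x) attr(x, "realized_rate")

mask_quota <- function(table, rate) {
  n_obs <- sum(!is.na(as_abund_matrix(table)))
  if (n_obs == 0) abort("The table has no observed cells.")
  n_mask <- as.integer(round_half_away(rate * n_obs))
  if (n_mask >= n_obs) {
    abort("`rate` would mask every observed cell of the table.")
  }
  n_mask
}

cells_tibble <- function(m, idx, mechanism, event) {
  tibble(
    sample_id = rownames(m)[(idx - 1L) %% nrow(m) + 1L],
    metabolite_id = colnames(m)[(idx - 1L) %/% nrow(m) + 1L],
    mechanism = mechanism,
    true_value = m[idx],
    event = event
  )
}

# -- mechanism workers --------------------------------------------------------
# Each takes the value matrix `m`, a logical `avail` matrix of cells that are
# observed and not yet masked, and a cell quota; returns linear indices (in
# masking order) plus an event id per cell. `avail` reflects earlier mixture
# stages so later mechanisms never re-mask a cell.

draw_mcar <- function(m, avail, quota) {
  pool <- which(avail)
  idx <- if (quota > 0) sample(pool, quota) else integer(0)
  list(idx = idx, event = rep(1L, length(idx)), events = NULL)
}

draw_mnar <- function(m, avail, quota, chisq_df, cap) {
  n_row <- nrow(m)
  orig_obs <- colSums(!is.na(m))
  cap_j <- floor(cap * orig_obs)
  masked_j <- integer(ncol(m))
  idx <- integer(0); ev <- integer(0); event <- 0L
  guard <- 0L
  while (length(idx) < quota) {
    guard <- guard + 1L
    if (guard > 50L * quota + 1000L) {
      abort("MNAR injection failed to reach the target rate (cap too tight).")
    }
    open <- colSums(avail) > 0 & masked_j < cap_j
    if (!any(open)) {
      abort("Requested MNAR rate is infeasible under the per-metabolite cap.")
    }
    j <- if (sum(open) == 1) which(open) else sample(which(open), 1)
    pct <- min(stats::rchisq(1, df = chisq_df), 100 * cap)
    k <- round_half_away(pct / 100 * orig_obs[j])
    k <- min(k, cap_j[j] - masked_j[j], sum(avail[, j]), quota - length(idx))
    if (k < 1) next
    event <- event + 1L
    rows <- which(avail[, j])
    # lowest observed values first; ties broken by sample index
    rows <- rows[order(m[rows, j], rows)][seq_len(k)]
    cell <- (j - 1L) * n_row + rows
    avail[cell] <- FALSE
    masked_j[j] <- masked_j[j] + k
    idx <- c(idx, cell); ev <- c(ev, rep(event, k))
  }
  list(idx = idx, event = ev, events = NULL)
}

draw_mar <- function(m, avail, quota, pct_range) {
  n_row <- nrow(m)
  if (ncol(m) < 2) abort("MAR injection needs at least 2 metabolites.")
  orig_obs <- colSums(!is.na(m))
  idx <- integer(0); ev <- integer(0); event <- 0L
  events <- list()
  guard <- 0L
  while (length(idx) < quota) {
    guard <- guard + 1L
    if (guard > 50L * quota + 1000L) {
      abort("MAR injection failed to reach the target rate.")
    }
    open <- colSums(avail) > 0
    if (!any(open)) abort("Requested MAR rate is infeasible.")
    tgt <- if (sum(open) == 1) which(open) else sample(which(open), 1)
    drv <- if (ncol(m) == 2) setdiff(1:2, tgt) else sample(setdiff(seq_len(ncol(m)), tgt), 1)
    pct <- stats::runif(1, pct_range[1], pct_range[2])
    k <- round_half_away(pct / 100 * orig_obs[tgt])
    k <- min(k, sum(avail[, tgt]), quota - length(idx))
    if (k < 1) next
    event <- event + 1L
    # samples ranked by the driver's abundance, highest first (NA last,
    # ties by sample index); take target cells down the ranking
    ord <- order(-m[, drv], seq_len(n_row), na.last = TRUE)
    rows <- ord[avail[ord, tgt]][seq_len(k)]
    cell <- (tgt - 1L) * n_row + rows
    avail[cell] <- FALSE
    idx <- c(idx, cell); ev <- c(ev, rep(event, k))
    events[[event]] <- tibble(
      event = event, driver = colnames(m)[drv], target = colnames(m)[tgt],
      n_cells = k
    )
  }
  list(idx = idx, event = ev, events = dplyr::bind_rows(events))
}

# -- public injectors ---------------------------------------------------------

#' Inject missing-completely-at-random values
#'
#' Masks exactly `round(rate * n_observed)` cells chosen uniformly without
#' replacement among observed cells, independent of all values.
#'
#' @inheritParams missingness_mask
#' @return A missingness mask (see [missingness_mask]).
#' @export
inject_mcar <- function(table, rate, seed) {
  validate_abund_tbl(table); check_rate(rate); seed <- check_seed(seed)
  m <- as_abund_matrix(table)
  quota <- mask_quota(table, rate)
  res <- withr::with_seed(seed, draw_mcar(m, !is.na(m), quota))
  new_miss_mask(cells_tibble(m, res$idx, "MCAR", res$event), table, rate, seed)
}

#' Inject missing-not-at-random values (detection-limit censoring)
#'
#' Repeatedly selects a metabolite at random, draws a per-metabolite
#' missingness percentage from a chi-squared(`chisq_df`) distribution
#' (interpreted as percent, capped at `cap` of the metabolite's observed
#' cells), and masks that metabolite's lowest observed values — emulating
#' abundances below the limit of detection. Selection continues (metabolites
#' may be revisited, accumulating up to the cap) until the global quota is
#' reached; the final draw is truncated, keeping the lowest cells.
#'
#' @inheritParams missingness_mask
#' @param chisq_df Degrees of freedom of the per-metabolite percentage draw.
#' @param cap Maximum fraction of a metabolite's observed cells that MNAR may
#'   mask.
#' @return A missingness mask.
#' @export
inject_mnar <- function(table, rate, seed, chisq_df = 6, cap = 0.8) {
  validate_abund_tbl(table); check_rate(rate); seed <- check_seed(seed)
  stopifnot(chisq_df > 0, cap > 0, cap <= 1)
  m <- as_abund_matrix(table)
  quota <- mask_quota(table, rate)
  if (quota > sum(floor(cap * colSums(!is.na(m))))) {
    abort("Requested MNAR rate is infeasible under the per-metabolite cap.")
  }
  res <- withr::with_seed(seed, draw_mnar(m, !is.na(m), quota, chisq_df, cap))
  new_miss_mask(cells_tibble(m, res$idx, "MNAR", res$event), table, rate, seed)
}

#' Inject missing-at-random values (abundant-neighbor interference)
#'
#' Repeatedly picks a random (driver, target) metabolite pair, draws a removal
#' percentage uniformly from `pct_range`, and masks the target's cells in the
#' samples where the driver's abundance ranks highest — emulating a co-eluting
#' abundant metabolite suppressing detection of another. Continues until the
#' global quota is reached.
#'
#' @inheritParams missingness_mask
#' @param pct_range Range (percent) of the per-pair removal percentage.
#' @return A missingness mask; per-event driver/target pairs are in
#'   `attr(, "events")`.
#' @export
inject_mar <- function(table, rate, seed, pct_range = c(5, 50)) {
  validate_abund_tbl(table); check_rate(rate); seed <- check_seed(seed)
  m <- as_abund_matrix(table)
  if (ncol(m) < 2) abort("MAR injection needs at least 2 metabolites.")
  quota <- mask_quota(table, rate)
  res <- withr::with_seed(seed, draw_mar(m, !is.na(m), quota, pct_range))
  new_miss_mask(cells_tibble(m, res$idx, "MAR", res$event), table, rate, seed,
                events = res$events)
}

#' Inject a mixture of MCAR, MAR and MNAR
#'
#' Applies the three mechanisms sequentially (MCAR, then MAR, then MNAR), each
#' contributing a third of the global quota (remainder cells assigned in that
#' fixed order, so mechanism counts differ pairwise by at most 1). Later
#' mechanisms only see still-observed cells, so no cell is masked twice; the
#' `mechanism` column records each cell's provenance.
#'
#' @inheritParams inject_mnar
#' @inheritParams inject_mar
#' @return A missingness mask.
#' @export
inject_mixture <- function(table, rate, seed, chisq_df = 6, cap = 0.8,
                           pct_range = c(5, 50)) {
  validate_abund_tbl(table); check_rate(rate); seed <- check_seed(seed)
  m <- as_abund_matrix(table)
  quota <- mask_quota(table, rate)
  base <- quota %/% 3L
  quotas <- base + (seq_len(3) <= quota %% 3L)
  seeds <- derive_seeds(seed, 3)
  avail <- !is.na(m)
  parts <- vector("list", 3)
  mechs <- c("MCAR", "MAR", "MNAR")
  for (i in 1:3) {
    res <- withr::with_seed(seeds[i], switch(
      mechs[i],
      MCAR = draw_mcar(m, avail, quotas[i]),
      MAR = draw_mar(m, avail, quotas[i], pct_range),
      MNAR = draw_mnar(m, avail, quotas[i], chisq_df, cap)
    ))
    avail[res$idx] <- FALSE
    parts[[i]] <- cells_tibble(m, res$idx, mechs[i], res$event)
  }
  new_miss_mask(dplyr::bind_rows(parts), table, rate, seed)
}

#' Mask a single observed cell
#'
#' The in-depth protocol: one previously observed cell is set missing, chosen
#' uniformly among observed cells not listed in `exclude`, and its true value
#' is recorded together with its host metabolite's context (percent
#' missingness and CV).
#'
#' @inheritParams missingness_mask
#' @param exclude Optional tibble of positions already used (`sample_id`,
#'   `metabolite_id`), e.g. the accumulated `position` rows of earlier draws,
#'   so repeated calls sample without replacement.
#' @return A list with `mask` (a one-cell missingness mask) and `position`
#'   (a one-row tibble: `sample_id`, `metabolite_id`, `true_value`,
#'   `pct_missing`, `cv` of the host metabolite).
#' @export
insert_single_missing <- function(table, seed, exclude = NULL) {
  validate_abund_tbl(table); seed <- check_seed(seed)
  m <- as_abund_matrix(table)
  avail <- !is.na(m)
  if (!is.null(exclude) && nrow(exclude)) {
    ri <- match(exclude$sample_id, rownames(m))
    ci <- match(exclude$metabolite_id, colnames(m))
    avail[cbind(ri, ci)] <- FALSE
  }
  pool <- which(avail)
  if (!length(pool)) abort("No eligible observed cells remain.")
  idx <- withr::with_seed(seed, if (length(pool) == 1) pool else sample(pool, 1))
  cells <- cells_tibble(m, idx, "MCAR", 1L)
  mask <- new_miss_mask(cells, table, 1 / sum(!is.na(m)), seed)
  ctx <- summarize_metabolites(table)
  ctx <- ctx[ctx$metabolite_id == cells$metabolite_id, ]
  list(
    mask = mask,
    position = tibble(
      sample_id = cells$sample_id, metabolite_id = cells$metabolite_id,
      true_value = cells$true_value,
      pct_missing = ctx$pct_missing, cv = ctx$cv
    )
  )
}

#' Drop metabolites above a missingness threshold
#'
#' @param table An [abundance_table()].
#' @param max_pct Retain metabolites with at most this percent missing
#'   (default 75, the usual pre-imputation filter).
#' @return The filtered table.
#' @export
filter_by_missingness <- function(table, max_pct = 75) {
  validate_abund_tbl(table)
  stopifnot(max_pct >= 0, max_pct <= 100)
  pct <- 100 * colMeans(is.na(as_abund_matrix(table)))
  keep <- metabolite_ids(table)[pct <= max_pct]
  new_abund_tbl(
    as_tibble(table)[, c("sample_id", keep), drop = FALSE],
    scale = table_scale(table), covariates = covariates(table)
  )
}

#' Apply or undo a missingness mask
#'
#' `apply_mask()` blanks the masked cells of a table; `restore_mask()` writes
#' the recorded true values back, exactly reconstructing the source table.
#'
#' @param table An [abundance_table()].
#' @param mask A missingness mask aligned to `table`.
#' @return The table with masked cells set to `NA` (or restored).
#' @export
apply_mask <- function(table, mask) {
  m <- as_abund_matrix(table)
  idx <- mask_indices(m, mask)
  if (any(is.na(m[idx]))) {
    abort("Mask targets a cell that is already missing in `table`.")
  }
  m[idx] <- NA
  abund_from_matrix(m, table)
}

#' @rdname apply_mask
#' @export
restore_mask <- function(table, mask) {
  m <- as_abund_matrix(table)
  m[mask_indices(m, mask)] <- mask$true_value
  abund_from_matrix(m, table)
}

mask_indices <- function(m, mask) {
  ri <- match(mask$sample_id, rownames(m))
  ci <- match(mask$metabolite_id, colnames(m))
  if (anyNA(ri) || anyNA(ci)) {
    abort("Mask refers to samples or metabolites absent from `table`.")
  }
  cbind(ri, ci)
}
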