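#' k-nearest-neighbor imputation
#'
#' For each metabolite with missing cells, the `k` nearest metabolites are
#' found by Euclidean distance over co-observed samples, normalized by the
#' number of co-observed samples (so sparsity does not shrink distances).
#' Each missing cell is the (optionally 1/distance-weighted) average of the
#' neighbor values observed in that sample. When no neighbor is observed in
#' the needed sample, the metabolite mean is used and the fallback recorded.
#'
#' @inheritParams impute
#' @param k Number of neighbor metabolites (must not exceed the number of
#'   other metabolites).
#' @param weighted Use 1/distance weights (default) or an unweighted average.
#' @return An `imputation_result`.
#' @export
impute_knn <- function(table, k = 10, weighted = TRUE) {
  m <- impute_setup(table)
  if (k < 1) abort("`k` must be at least 1.")
  if (!anyNA(m)) {
    return(new_imputation_result(table, m, "knn", list(k = k, weighted = weighted)))
  }
  if (k > ncol(m) - 1) {
    abort(sprintf("k = %d exceeds the %d other metabolites available.",
                  k, ncol(m) - 1))
  }
  out <- m
  fallbacks <- character(0)
  d <- knn_distances(m)
  mu <- colMeans(m, na.rm = TRUE)
  for (t in which(colSums(is.na(m)) > 0)) {
    dt <- d[, t]
    dt[t] <- Inf
    nb <- order(dt, seq_along(dt))[seq_len(k)]
    nb <- nb[is.finite(dt[nb])]
    w_nb <- if (weighted) 1 / (dt[nb] + 1e-12) else rep(1, length(nb))
    for (s in which(is.na(m[, t]))) {
      v <- m[s, nb]
      ok <- !is.na(v)
      if (!length(nb) || !any(ok)) {
        out[s, t] <- mu[t]
        fallbacks <- c(fallbacks, sprintf("%s@%s", colnames(m)[t], rownames(m)[s]))
      } else {
        out[s, t] <- sum(v[ok] * w_nb[ok]) / sum(w_nb[ok])
      }
    }
  }
  new_imputation_result(table, out, "knn", list(k = k, weighted = weighted),
                        diagnostics = list(fallbacks = fallbacks))
}

# pairwise metabolite distances: sqrt(mean squared difference over co-observed
# samples); Inf when no sample is co-observed
knn_distances <- function(m) {
  p <- ncol(m)
  d <- matrix(Inf, p, p)
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      co <- !is.na(m[, a]) & !is.na(m[, b])
      if (any(co)) {
        d[a, b] <- d[b, a] <- sqrt(mean((m[co, a] - m[co, b])^2))
      }
    }
  }
  diag(d) <- 0
  d
}

#' Local-least-squares imputation
#'
#' For each metabolite with missing cells, the `k` metabolites most correlated
#' with it (absolute Pearson correlation over co-observed samples) form a
#' local linear model: ordinary least squares of the target on the neighbors,
#' fitted on the samples where target and all neighbors are observed. Missing
#' cells are predicted from the neighbors (neighbor gaps mean-filled at
#' prediction time). When fewer than `k + 2` complete rows exist or the design
#' is rank-deficient, the metabolite falls back to mean imputation and the
#' fallback is recorded — never a silent failure.
#'
#' @inheritParams impute
#' @param k Number of neighbor metabolites.
#' @return An `imputation_result`.
#' @export
impute_lls <- function(table, k = 10) {
  m <- impute_setup(table)
  if (k < 1) abort("`k` must be at least 1.")
  if (!anyNA(m)) {
    return(new_imputation_result(table, m, "lls", list(k = k)))
  }
  k <- min(k, ncol(m) - 1)
  out <- m
  mu <- colMeans(m, na.rm = TRUE)
  fallbacks <- character(0)
  cors <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  for (t in which(colSums(is.na(m)) > 0)) {
    ct <- abs(cors[, t])
    ct[t] <- -Inf
    ct[is.na(ct)] <- -Inf
    nb <- order(-ct, seq_along(ct))[seq_len(k)]
    nb <- nb[is.finite(ct[nb])]
    fit_rows <- which(!is.na(m[, t]) & rowSums(is.na(m[, nb, drop = FALSE])) == 0)
    coef <- NULL
    if (length(nb) && length(fit_rows) >= length(nb) + 2) {
      X <- cbind(1, m[fit_rows, nb, drop = FALSE])
      qx <- qr(X)
      if (qx$rank == ncol(X)) {
        coef <- qr.coef(qx, m[fit_rows, t])
      }
    }
    miss_rows <- which(is.na(m[, t]))
    if (is.null(coef)) {
      out[miss_rows, t] <- mu[t]
      fallbacks <- c(fallbacks, colnames(m)[t])
    } else {
      N <- m[miss_rows, nb, drop = FALSE]
      for (j in seq_along(nb)) N[is.na(N[, j]), j] <- mu[nb[j]]
      out[miss_rows, t] <- cbind(1, N) %*% coef
    }
  }
  new_imputation_result(table, out, "lls", list(k = k),
                        diagnostics = list(fallbacks = fallbacks))
}
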