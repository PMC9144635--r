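#' Iterative truncated-SVD imputation
#'
#' Low-rank matrix completion by alternating projection: missing cells are
#' initialized with metabolite means, then the table is repeatedly replaced by
#' its truncated rank-`rank` reconstruction on the missing cells only
#' (observed cells are re-imposed each pass) until the largest relative change
#' in an imputed cell drops below `tol` or `max_iter` passes elapse.
#'
#' @inheritParams impute
#' @param rank Reconstruction rank, in `[1, min(dim) - 1)`.
#' @param max_iter Maximum alternating passes.
#' @param tol Convergence tolerance on the imputed cells.
#' @return An `imputation_result`; the per-iteration change trace is in
#'   `diagnostics$trace` and `converged` is `FALSE` on non-convergence.
#' @export
impute_svd <- function(table, rank = 5, max_iter = 100, tol = 1e-5) {
  m <- impute_setup(table)
  if (rank < 1 || rank >= min(dim(m))) {
    abort("`rank` must satisfy 1 <= rank < min(n_samples, n_metabolites).")
  }
  miss <- is.na(m)
  if (!any(miss)) {
    return(new_imputation_result(table, m, "svd", list(rank = rank)))
  }
  cur <- col_mean_fill(m)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  scale_ref <- max(abs(m), na.rm = TRUE)
  for (iter in seq_len(max_iter)) {
    sv <- svd(cur, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    delta <- max(abs(recon[miss] - cur[miss])) / max(scale_ref, 1e-12)
    cur[miss] <- recon[miss]
    trace <- c(trace, delta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  new_imputation_result(table, cur, "svd",
                        list(rank = rank, max_iter = max_iter, tol = tol),
                        n_iterations = iter, converged = converged,
                        diagnostics = list(trace = trace))
}

#' Bayesian PCA imputation
#'
#' Variational Bayesian principal component analysis with missing data, in
#' the style of Oba et al.: a probabilistic PCA model
#' `y = W x + mu + eps` is fitted by EM, computing each sample's latent
#' posterior from its observed coordinates only, with an automatic relevance
#' determination (ARD) prior on the loading columns that shrinks superfluous
#' components away. Missing cells are the posterior-mean reconstruction.
#' Initialization (mean fill + SVD) is deterministic, so the result is a pure
#' function of the input; `seed` is recorded for provenance.
#'
#' @inheritParams impute
#' @param n_components Number of latent components; default
#'   `min(dim) - 1`, relying on ARD to prune.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the imputed cells.
#' @return An `imputation_result`.
#' @export
impute_bpca <- function(table, n_components = NULL, max_iter = 200,
                        tol = 1e-5, seed = 1) {
  m <- impute_setup(table)
  n <- nrow(m); d <- ncol(m)
  q <- n_components %||% (min(n, d) - 1L)
  if (q < 1 || q >= min(n, d)) {
    abort("`n_components` must satisfy 1 <= q < min(n_samples, n_metabolites).")
  }
  miss <- is.na(m)
  if (!any(miss)) {
    return(new_imputation_result(table, m, "bpca", list(n_components = q),
                                 seed = check_seed(seed)))
  }
  fill <- col_mean_fill(m)
  mu <- colMeans(fill)
  yc <- sweep(fill, 2, mu)
  sv <- svd(yc, nu = q, nv = q)
  W <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(n), q, q) # d x q loadings
  tau <- 1 / max(mean(yc^2) * 0.1, 1e-8)
  alpha <- rep(1, q)
  obs_rows <- apply(!miss, 1, which)
  if (is.matrix(obs_rows)) obs_rows <- as.list(as.data.frame(obs_rows))
  converged <- FALSE
  iter <- 0L
  scale_ref <- max(abs(m), na.rm = TRUE)
  for (iter in seq_len(max_iter)) {
    X <- matrix(0, n, q)
    Ssum <- matrix(0, q, q)
    new_fill <- fill
    for (i in seq_len(n)) {
      o <- obs_rows[[i]]
      Wo <- W[o, , drop = FALSE]
      P <- diag(q) + tau * crossprod(Wo)
      Si <- chol2inv(chol(P))
      mi <- tau * Si %*% crossprod(Wo, m[i, o] - mu[o])
      X[i, ] <- mi
      Ssum <- Ssum + Si
      mis <- which(miss[i, ])
      if (length(mis)) {
        new_fill[i, mis] <- mu[mis] + W[mis, , drop = FALSE] %*% mi
      }
    }
    delta <- max(abs(new_fill[miss] - fill[miss])) / max(scale_ref, 1e-12)
    fill <- new_fill
    # M-step on the completed data, ARD-penalized loadings
    mu <- colMeans(fill)
    yc <- sweep(fill, 2, mu)
    B <- crossprod(X) + Ssum + diag(alpha, q) / tau
    W <- t(solve(B, crossprod(X, yc)))
    resid <- yc - X %*% t(W)
    tau <- (n * d) / (sum(resid^2) + sum(diag(crossprod(W) %*% Ssum)) + 1e-12)
    alpha <- d / (colSums(W^2) + 1e-8)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  new_imputation_result(
    table, fill, "bpca",
    list(n_components = q, max_iter = max_iter, tol = tol),
    n_iterations = iter, converged = converged, seed = check_seed(seed),
    diagnostics = list(alpha = alpha, tau = tau)
  )
}
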