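# Iterative model-based imputers: each metabolite is regressed on all others
# over the current completed matrix, looping until the imputed values settle.
# Columns are variables, rows (samples) are observations throughout.

#' Random-forest imputation
#'
#' missForest-style chained imputation: missing cells are initialized with
#' metabolite means; metabolites are then visited in increasing order of
#' missingness, each regressed on all other metabolites with a random forest
#' fitted on its observed rows and its missing rows re-predicted. Passes
#' repeat until the sum of squared changes in the imputed values first
#' *increases* (the matrix from the previous pass is returned) or `max_iter`
#' is reached.
#'
#' @inheritParams impute
#' @param n_trees Trees per forest.
#' @param max_iter Maximum passes over the metabolites.
#' @return An `imputation_result`.
#' @export
impute_rf <- function(table, n_trees = 100, max_iter = 10, seed = 1) {
  m <- impute_setup(table)
  if (ncol(m) < 2) abort("Random-forest imputation needs >= 2 metabolites.")
  seed <- check_seed(seed)
  miss <- is.na(m)
  if (!any(miss)) {
    return(new_imputation_result(table, m, "rf", list(n_trees = n_trees),
                                 n_iterations = 0L, seed = seed))
  }
  cur <- col_mean_fill(m)
  targets <- which(colSums(miss) > 0)
  targets <- targets[order(colSums(miss)[targets])]
  seeds <- derive_seeds(seed, max_iter * length(targets))
  prev <- cur
  prev_delta <- Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    before <- cur
    for (ti in seq_along(targets)) {
      t <- targets[ti]
      obs <- !miss[, t]
      fit <- ranger::ranger(
        x = as.data.frame(cur[obs, -t, drop = FALSE]),
        y = cur[obs, t],
        num.trees = n_trees, num.threads = 1,
        seed = seeds[(iter - 1L) * length(targets) + ti]
      )
      pred <- stats::predict(
        fit, data = as.data.frame(cur[!obs, -t, drop = FALSE]),
        num.threads = 1
      )$predictions
      cur[!obs, t] <- pred
    }
    delta <- sum((cur[miss] - before[miss])^2) / max(sum(cur[miss]^2), 1e-12)
    if (delta > prev_delta) {
      cur <- before # first increase: keep the previous pass
      iter <- iter - 1L
      break
    }
    prev_delta <- delta
    if (delta < 1e-8) break
  }
  new_imputation_result(table, cur, "rf",
                        list(n_trees = n_trees, max_iter = max_iter),
                        n_iterations = iter, converged = TRUE, seed = seed)
}

#' Ridge-regression imputation
#'
#' Chained imputation with L2-penalized linear models (glmnet, `alpha = 0`):
#' each metabolite with missing cells is regressed on all others over the
#' current completed matrix, with the penalty chosen per metabolite by
#' internal cross-validation over `lambda_grid` (a single-value grid skips the
#' cross-validation and uses that penalty directly). The penalty is selected
#' on the first pass and reused on later passes, which only refresh the fit
#' on the updated completed matrix. Passes repeat until the largest relative
#' change in an imputed cell falls below `tol`.
#'
#' @inheritParams impute
#' @param lambda_grid Candidate penalties for the internal cross-validation.
#' @param max_iter Maximum passes.
#' @param tol Convergence tolerance on imputed cells.
#' @param n_folds Folds for the internal cross-validation.
#' @return An `imputation_result`.
#' @export
impute_grr <- function(table, lambda_grid = 10^seq(-4, 2, length.out = 25),
                       max_iter = 10, tol = 1e-4, n_folds = 5, seed = 1) {
  m <- impute_setup(table)
  if (ncol(m) < 2) abort("Ridge imputation needs >= 2 metabolites.")
  seed <- check_seed(seed)
  miss <- is.na(m)
  if (!any(miss)) {
    return(new_imputation_result(table, m, "grr", list(), seed = seed))
  }
  lambda_grid <- sort(as.numeric(lambda_grid), decreasing = TRUE)
  cur <- col_mean_fill(m)
  targets <- which(colSums(miss) > 0)
  seeds <- derive_seeds(seed, length(targets))
  lambda_sel <- rep(NA_real_, length(targets))
  scale_ref <- max(abs(m), na.rm = TRUE)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    before <- cur
    for (ti in seq_along(targets)) {
      t <- targets[ti]
      obs <- !miss[, t]
      x <- cur[obs, -t, drop = FALSE]
      y <- cur[obs, t]
      newx <- cur[!obs, -t, drop = FALSE]
      grid_t <- if (is.na(lambda_sel[ti])) lambda_grid else lambda_sel[ti]
      fit <- ridge_predict(x, y, newx, grid_t, n_folds, seeds[ti])
      lambda_sel[ti] <- fit$lambda
      cur[!obs, t] <- fit$pred
    }
    delta <- max(abs(cur[miss] - before[miss])) / max(scale_ref, 1e-12)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  new_imputation_result(
    table, cur, "grr",
    list(lambda_grid = lambda_grid, max_iter = max_iter, tol = tol,
         n_folds = n_folds),
    n_iterations = iter, converged = converged, seed = seed
  )
}

#' Quantile-regression imputation
#'
#' Chained imputation with per-metabolite linear quantile regression: each
#' metabolite with missing cells is regressed on all others by minimizing the
#' pinball (check) loss at the requested `quantile`, and its missing cells
#' become the predicted conditional quantile. The fit uses iteratively
#' reweighted least squares on the check loss with a small ridge term for
#' numerical stability; degenerate designs fall back to mean imputation, and
#' every fallback is recorded.
#'
#' @inheritParams impute
#' @param quantile Conditional quantile in (0, 1); 0.5 gives median
#'   regression.
#' @param max_iter Maximum chained passes.
#' @return An `imputation_result`.
#' @export
impute_qr <- function(table, quantile = 0.5, max_iter = 5, seed = 1) {
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile <= 0 || quantile >= 1) {
    abort("`quantile` must lie strictly between 0 and 1.")
  }
  m <- impute_setup(table)
  if (ncol(m) < 2) abort("Quantile-regression imputation needs >= 2 metabolites.")
  seed <- check_seed(seed)
  miss <- is.na(m)
  if (!any(miss)) {
    return(new_imputation_result(table, m, "qr", list(quantile = quantile),
                                 seed = seed))
  }
  cur <- col_mean_fill(m)
  targets <- which(colSums(miss) > 0)
  mu <- colMeans(m, na.rm = TRUE)
  fallbacks <- character(0)
  scale_ref <- max(abs(m), na.rm = TRUE)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    before <- cur
    for (t in targets) {
      obs <- !miss[, t]
      beta <- fit_pinball(cur[obs, -t, drop = FALSE], cur[obs, t], quantile)
      if (is.null(beta)) {
        cur[!obs, t] <- mu[t]
        fallbacks <- c(fallbacks, colnames(m)[t])
      } else {
        cur[!obs, t] <- cbind(1, cur[!obs, -t, drop = FALSE]) %*% beta
      }
    }
    delta <- max(abs(cur[miss] - before[miss])) / max(scale_ref, 1e-12)
    if (delta < 1e-5) break
  }
  new_imputation_result(
    table, cur, "qr", list(quantile = quantile, max_iter = max_iter),
    n_iterations = iter, converged = TRUE, seed = seed,
    diagnostics = list(fallbacks = unique(fallbacks))
  )
}

# ridge prediction for one target: glmnet for >= 2 predictors (cv over the
# grid unless it has a single value), closed form on standardized variables
# for the single-predictor case glmnet does not accept; returns the
# prediction and the penalty used so callers can reuse it
ridge_predict <- function(x, y, newx, lambda_grid, n_folds, fold_seed) {
  # few observed values cannot support cross-validation: fall back to the
  # middle of the grid rather than fitting folds of 1-2 points
  n_folds <- max(2L, min(n_folds, floor(length(y) / 3)))
  if (length(y) < 8 && length(lambda_grid) > 1) {
    lambda_grid <- lambda_grid[ceiling(length(lambda_grid) / 2)]
  }
  if (ncol(x) >= 2) {
    if (length(lambda_grid) == 1) {
      fit <- glmnet::glmnet(x, y, alpha = 0, lambda = lambda_grid)
      return(list(pred = as.numeric(stats::predict(fit, newx = newx)),
                  lambda = lambda_grid))
    }
    foldid <- withr::with_seed(
      fold_seed, sample(rep_len(seq_len(n_folds), length(y)))
    )
    cv <- glmnet::cv.glmnet(x, y, alpha = 0, lambda = lambda_grid,
                            foldid = foldid)
    return(list(
      pred = as.numeric(stats::predict(cv, newx = newx, s = "lambda.min")),
      lambda = cv$lambda.min
    ))
  }
  xv <- x[, 1]; nx <- newx[, 1]
  pred_1d <- function(lambda) {
    sx <- sqrt(mean((xv - mean(xv))^2))
    if (sx == 0) return(rep(mean(y), length(nx)))
    z <- (xv - mean(xv)) / sx
    b <- mean(z * (y - mean(y))) / (mean(z^2) + lambda)
    mean(y) + b * (nx - mean(xv)) / sx
  }
  if (length(lambda_grid) == 1) {
    return(list(pred = pred_1d(lambda_grid[1]), lambda = lambda_grid[1]))
  }
  folds <- withr::with_seed(
    fold_seed, sample(rep_len(seq_len(n_folds), length(y)))
  )
  cv_err <- vapply(lambda_grid, function(l) {
    se <- 0
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (sum(tr) < 2 || !any(!tr)) next
      sx <- sqrt(mean((xv[tr] - mean(xv[tr]))^2))
      pr <- if (sx == 0) rep(mean(y[tr]), sum(!tr)) else {
        z <- (xv[tr] - mean(xv[tr])) / sx
        b <- mean(z * (y[tr] - mean(y[tr]))) / (mean(z^2) + l)
        mean(y[tr]) + b * (xv[!tr] - mean(xv[tr])) / sx
      }
      se <- se + sum((y[!tr] - pr)^2)
    }
    se
  }, numeric(1))
  lam <- lambda_grid[which.min(cv_err)]
  list(pred = pred_1d(lam), lambda = lam)
}

# pinball-loss linear fit by iteratively reweighted least squares with a tiny
# ridge; returns NULL on degenerate input
fit_pinball <- function(x, y, tau, n_iter = 40, ridge = 1e-6) {
  X <- cbind(1, x)
  if (nrow(X) <= ncol(X) || stats::var(y) == 0) return(NULL)
  XtX_ok <- TRUE
  beta <- tryCatch(
    solve(crossprod(X) + diag(ridge, ncol(X)), crossprod(X, y)),
    error = function(e) { XtX_ok <<- FALSE; NULL }
  )
  if (!XtX_ok) return(NULL)
  eps <- 1e-6 * max(stats::sd(y), 1e-12)
  for (i in seq_len(n_iter)) {
    r <- as.numeric(y - X %*% beta)
    # asymmetric Huber-type weights approximating the check loss
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    new_beta <- tryCatch(
      solve(crossprod(X, w * X) + diag(ridge, ncol(X)), crossprod(X, w * y)),
      error = function(e) NULL
    )
    if (is.null(new_beta)) return(beta)
    if (max(abs(new_beta - beta)) < 1e-10) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta
}
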