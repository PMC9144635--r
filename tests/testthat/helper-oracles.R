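# Brute-force reference implementations, written directly from the method
# contracts with plain loops. They exist to cross-check the package's
# (vectorized) imputers on tiny tables and stay deliberately naive.

oracle_knn <- function(m, k, weighted = TRUE) {
  n <- nrow(m); p <- ncol(m)
  out <- m
  for (t in seq_len(p)) {
    if (!anyNA(m[, t])) next
    d <- rep(Inf, p)
    for (j in seq_len(p)) {
      if (j == t) next
      co <- which(!is.na(m[, j]) & !is.na(m[, t]))
      if (length(co)) d[j] <- sqrt(sum((m[co, j] - m[co, t])^2) / length(co))
    }
    nb <- setdiff(order(d, seq_len(p)), t)[seq_len(k)]
    nb <- nb[is.finite(d[nb])]
    for (s in which(is.na(m[, t]))) {
      vals <- c(); wts <- c()
      for (j in nb) {
        if (!is.na(m[s, j])) {
          vals <- c(vals, m[s, j])
          wts <- c(wts, if (weighted) 1 / (d[j] + 1e-12) else 1)
        }
      }
      out[s, t] <- if (length(vals)) {
        sum(vals * wts) / sum(wts)
      } else {
        mean(m[, t], na.rm = TRUE)
      }
    }
  }
  out
}

oracle_lls <- function(m, k) {
  n <- nrow(m); p <- ncol(m)
  k <- min(k, p - 1)
  out <- m
  mu <- colMeans(m, na.rm = TRUE)
  for (t in seq_len(p)) {
    if (!anyNA(m[, t])) next
    r <- rep(-Inf, p)
    for (j in seq_len(p)) {
      if (j == t) next
      cj <- suppressWarnings(cor(m[, j], m[, t], use = "pairwise.complete.obs"))
      if (!is.na(cj)) r[j] <- abs(cj)
    }
    nb <- order(-r, seq_len(p))[seq_len(k)]
    nb <- nb[is.finite(r[nb])]
    rows <- which(!is.na(m[, t]))
    for (j in nb) rows <- rows[!is.na(m[rows, j])]
    miss <- which(is.na(m[, t]))
    if (length(nb) == 0 || length(rows) < length(nb) + 2) {
      out[miss, t] <- mu[t]
      next
    }
    X <- cbind(1, m[rows, nb, drop = FALSE])
    if (qr(X)$rank < ncol(X)) {
      out[miss, t] <- mu[t]
      next
    }
    beta <- solve(t(X) %*% X, t(X) %*% m[rows, t])
    for (s in miss) {
      xs <- c(1, m[s, nb])
      for (jj in seq_along(nb)) {
        if (is.na(xs[jj + 1])) xs[jj + 1] <- mu[nb[jj]]
      }
      out[s, t] <- sum(xs * beta)
    }
  }
  out
}

# mean of pairwise correlations by explicit pair enumeration
oracle_mean_pairwise_cor <- function(vectors) {
  k <- length(vectors)
  vals <- c()
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      vals <- c(vals, cor(vectors[[a]], vectors[[b]]))
    }
  }
  mean(vals)
}
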