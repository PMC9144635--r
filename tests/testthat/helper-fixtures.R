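# small fixtures built in code ----------------------------------------------

tiny_table <- function(values, scale = "raw", covariates = NULL) {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("m%d", seq_len(ncol(m)))
  abundance_table(m, scale = scale, covariates = covariates)
}

# reproducible random table with a chosen missingness pattern (log10 scale)
random_log_table <- function(n = 8, p = 6, n_miss = 5, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p, mean = 5, sd = 0.5), n, p)
    idx <- sample(n * p, n_miss)
  })
  m[idx] <- NA
  # keep every metabolite partly observed
  for (j in seq_len(p)) if (all(is.na(m[, j]))) m[1, j] <- 5
  dimnames(m) <- list(sprintf("s%d", seq_len(n)), sprintf("m%d", seq_len(p)))
  abundance_table(m, scale = "log10")
}
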