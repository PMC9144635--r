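mask_all <- function(tb) {
  m <- as_abund_matrix(tb)
  idx <- which(!is.na(m))
  structure(
    tibble::tibble(
      sample_id = rownames(m)[(idx - 1) %% nrow(m) + 1],
      metabolite_id = colnames(m)[(idx - 1) %/% nrow(m) + 1],
      mechanism = "MCAR", true_value = m[idx], event = 1L
    ),
    class = c("miss_mask", class(tibble::tibble()))
  )
}

test_that("rmse and percent bias are computed over masked cells only", {
  truth <- tiny_table(matrix(c(1, 2), 1, 2), scale = "log10")
  imp <- tiny_table(matrix(c(2, 4), 1, 2), scale = "log10")
  mk <- mask_all(truth)
  expect_equal(rmse(truth, imp, mk), sqrt(5 / 2), tolerance = 1e-12)
  expect_equal(rmse(truth, truth, mk), 0)
  expect_equal(percent_bias(truth, truth, mk), 0)

  # truth 10 imputed 9 -> 10%; two cells at 5% and 15% average to 10%
  t2 <- tiny_table(matrix(c(10, 20), 1, 2), scale = "log10")
  i2 <- tiny_table(matrix(c(9, 20), 1, 2), scale = "log10")
  mk1 <- mask_all(t2)[1, ]
  expect_equal(percent_bias(t2, i2, mk1), 10)
  i3 <- tiny_table(matrix(c(10 * 1.05, 20 * 0.85), 1, 2), scale = "log10")
  expect_equal(percent_bias(t2, i3, mask_all(t2)), 10, tolerance = 1e-9)

  # perturbing unmasked cells changes nothing
  big <- random_log_table(n = 6, p = 4, n_miss = 0, seed = 1)
  mk <- mask_all(big)[1:5, ]
  imp_m <- as_abund_matrix(big)
  idx <- cbind(match(mk$sample_id, big$sample_id),
               match(mk$metabolite_id, metabolite_ids(big)))
  imp_m[idx] <- imp_m[idx] + 0.5
  imp1 <- tiny_table(imp_m, scale = "log10")
  imp_m[6, 4] <- 999
  imp2 <- tiny_table(imp_m, scale = "log10")
  expect_equal(rmse(big, imp1, mk), rmse(big, imp2, mk))
  expect_equal(percent_bias(big, imp1, mk), percent_bias(big, imp2, mk))

  expect_error(rmse(big, imp1, mk[0, ]), "empty")
  zero_truth <- tiny_table(matrix(c(0, 1), 1, 2), scale = "log10")
  expect_error(percent_bias(zero_truth, imp, mask_all(zero_truth)), "zero")
})

test_that("Cronbach's alpha matches closed forms", {
  # two items with unit variances and covariance 0.5: alpha = 2/3
  withr::local_seed(5)
  z <- matrix(rnorm(4000), 2000, 2)
  z[, 2] <- 0.5 * z[, 1] + sqrt(1 - 0.25) * z[, 2]
  # rescale to make the sample moments exact
  z <- scale(z)
  r <- cor(z[, 1], z[, 2])
  alpha_expect <- 2 * (1 - 2 / (2 + 2 * r))
  tb <- tiny_table(t(z) + 5, scale = "log10") # items = samples (rows)
  expect_equal(cronbach_alpha(tb, "samples"), alpha_expect, tolerance = 1e-10)

  # identical items give alpha = 1
  dup <- tiny_table(rbind(a = c(1, 2, 3), b = c(1, 2, 3)) + 0, scale = "log10")
  expect_equal(cronbach_alpha(dup, "samples"), 1)

  # independent items: alpha near 0 over replicates
  alphas <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      m <- matrix(rnorm(5 * 400), 400, 5)
      cronbach_alpha(tiny_table(m, scale = "log10"), "metabolites")
    })
  }, numeric(1))
  expect_lt(mean(abs(alphas)), 0.1)

  # standardized equicorrelated items: alpha = k*r / (1 + (k-1)*r)
  for (rbar in c(0, 0.5, 0.9)) {
    k <- 4
    sigma <- matrix(rbar, k, k); diag(sigma) <- 1
    ch <- chol(sigma)
    withr::local_seed(7)
    z <- scale(matrix(rnorm(k * 5000), 5000, k) %*% ch)
    cc <- cor(z)
    r_emp <- mean(cc[upper.tri(cc)])
    expect_equal(
      cronbach_alpha(tiny_table(z + 9, scale = "log10"), "metabolites"),
      k * r_emp / (1 + (k - 1) * r_emp),
      tolerance = 1e-6
    )
  }

  expect_error(cronbach_alpha(tiny_table(matrix(1, 3, 3), scale = "log10"),
                              "samples"), "variance")
})

test_that("mean pairwise correlation matches pair enumeration", {
  s1 <- c(1, 2, 3); s2 <- c(3, 2, 1)
  tb <- tiny_table(rbind(s1, s2) + 0, scale = "log10")
  expect_equal(mean_pairwise_correlation(tb, "samples"), -1)

  dup <- tiny_table(rbind(c(1, 5, 3), c(1, 5, 3)) + 0, scale = "log10")
  expect_equal(mean_pairwise_correlation(dup, "samples"), 1)

  withr::local_seed(11)
  m <- matrix(rnorm(15, 5), 3, 5)
  tb3 <- tiny_table(m, scale = "log10")
  expect_equal(
    mean_pairwise_correlation(tb3, "samples"),
    oracle_mean_pairwise_cor(list(m[1, ], m[2, ], m[3, ])),
    tolerance = 1e-12
  )

  with_const <- tiny_table(rbind(c(1, 2, 3), c(2, 2, 2), c(3, 1, 2)) + 0,
                           scale = "log10")
  expect_warning(mean_pairwise_correlation(with_const, "samples"), "constant")
})

test_that("regression bias is exactly zero on truth vs truth", {
  bio <- log10_transform(simulate_biological(n_samples = 20,
                                             n_metabolites = 15, seed = 2))
  rb <- regression_bias(bio, bio)
  expect_equal(nrow(rb), 15)
  expect_true(all(rb$beta_diff == 0))
  expect_true(all(rb$p_diff == 0))
  expect_true(all(rb$p_true >= 0 & rb$p_true <= 1))
})

test_that("regression slopes match the normal-equation oracle", {
  age <- c(2, 5, 9, 14)
  y <- c(1.0, 1.4, 2.1, 2.9)
  cov <- tibble::tibble(sample_id = paste0("s", 1:4), age = age)
  tb <- tiny_table(matrix(y, 4, 1, dimnames = list(paste0("s", 1:4), "m1")),
                   scale = "log10", covariates = cov)
  rb <- regression_bias(tb, tb)
  X <- cbind(1, age)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)[2]
  expect_equal(rb$beta_true, beta_hat, tolerance = 1e-12)
  fit <- summary(lm(y ~ age))
  expect_equal(rb$p_true, fit$coefficients["age", 4], tolerance = 1e-12)
})

test_that("one-sample t matches the hand formula", {
  r <- one_sample_t(c(-1, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r2 <- one_sample_t(c(1, 2, 3))
  expect_equal(r2$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r2$p, 0.0742, tolerance = 1e-3)
  expect_error(one_sample_t(c(2, 2, 2)), "Zero standard deviation")
  expect_error(one_sample_t(3), "at least 2")
})

test_that("pairwise Wilcoxon gives exact small-sample p and a symmetric matrix", {
  g <- list(a = c(1, 2, 3), b = c(10, 11, 12), c = c(1.5, 2.5, 3.5))
  p <- pairwise_wilcoxon(g)
  expect_equal(p["a", "b"], 0.1, tolerance = 1e-12) # most extreme 3v3 ranking
  expect_identical(p, t(p))
  expect_true(all(is.na(diag(p))))

  same <- list(x = 1:6 + 0.5, y = 1:6 + 0.5)
  expect_gt(suppressWarnings(pairwise_wilcoxon(same))["x", "y"], 0.9)
  expect_error(pairwise_wilcoxon(list(a = 1:3)), "at least 2")
  expect_error(pairwise_wilcoxon(list(a = 1:3, b = numeric(0))), "Empty")
})

test_that("BH adjustment matches the step-up rule and its properties", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::local_seed(13)
  p <- runif(50)^2
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone in the order statistics
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})
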