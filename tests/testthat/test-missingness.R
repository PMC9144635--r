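complete_150x60 <- function() {
  log10_transform(simulate_replicates(seed = 101))
}

test_that("MCAR masks the exact cell count and rate 0 gives an empty mask", {
  tb <- complete_150x60()
  mk <- inject_mcar(tb, 0.10, seed = 1)
  expect_equal(nrow(mk), 900) # 0.10 x 9000
  expect_equal(realized_rate(mk), 0.10)
  expect_equal(nrow(inject_mcar(tb, 0, seed = 1)), 0)
  expect_error(inject_mcar(tb, 1, seed = 1), "must be")
})

test_that("MCAR cell choice is uniform across positions", {
  tb <- random_log_table(n = 10, p = 10, n_miss = 0, seed = 2)
  counts <- matrix(0, 10, 10)
  for (s in seq_len(2000)) {
    mk <- inject_mcar(tb, 0.1, seed = s)
    idx <- cbind(match(mk$sample_id, tb$sample_id),
                 match(mk$metabolite_id, metabolite_ids(tb)))
    counts[idx] <- counts[idx] + 1
  }
  gof <- stats::chisq.test(as.vector(counts))
  expect_gt(gof$p.value, 0.001)
})

test_that("MNAR masks only within-metabolite minima and books rates exactly", {
  tb <- random_log_table(n = 30, p = 12, n_miss = 0, seed = 3)
  m <- as_abund_matrix(tb)
  for (s in 1:25) {
    mk <- inject_mnar(tb, 0.2, seed = s)
    expect_equal(nrow(mk), round(0.2 * length(m)))
    expect_lte(abs(realized_rate(mk) - 0.2), 1 / length(m))
    masked <- apply_mask(tb, mk)
    mm <- as_abund_matrix(masked)
    for (j in unique(match(mk$metabolite_id, colnames(m)))) {
      gone <- m[is.na(mm[, j]), j]
      kept <- m[!is.na(mm[, j]), j]
      if (length(kept)) expect_lte(max(gone), min(kept))
    }
  }
  expect_equal(nrow(inject_mnar(tb, 0, seed = 1)), 0)
})

test_that("MNAR signature: masked values sit below unmasked within each metabolite", {
  tb <- complete_150x60()
  m <- as_abund_matrix(tb)
  mk <- inject_mnar(tb, 0.15, seed = 9)
  masked <- as_abund_matrix(apply_mask(tb, mk))
  for (j in unique(match(mk$metabolite_id, colnames(m)))) {
    expect_lt(mean(m[is.na(masked[, j]), j]), mean(m[!is.na(masked[, j]), j]))
  }
})

test_that("infeasible MNAR rates error instead of spinning", {
  tb <- random_log_table(n = 10, p = 4, n_miss = 0, seed = 4)
  expect_error(inject_mnar(tb, 0.6, seed = 1, cap = 0.5), "infeasible")
})

test_that("MAR events mask the target rows with the highest driver abundances", {
  tb <- random_log_table(n = 40, p = 6, n_miss = 0, seed = 5)
  m <- as_abund_matrix(tb)
  mk <- inject_mar(tb, 0.08, seed = 6)
  ev <- attr(mk, "events")
  expect_true(all(c("driver", "target", "n_cells") %in% names(ev)))
  first <- ev[1, ]
  cells <- mk[mk$event == 1 & mk$metabolite_id == first$target, ]
  drv_rank <- rank(-m[, first$driver], ties.method = "first")
  expect_setequal(
    drv_rank[match(cells$sample_id, rownames(m))],
    seq_len(first$n_cells)
  )
  expect_error(
    inject_mar(tiny_table(matrix(1:4, 4, 1)), 0.2, seed = 1),
    "at least 2 metabolites"
  )
  expect_equal(nrow(inject_mar(tb, 0, seed = 1)), 0)
})

test_that("MAR dependence signature: driver abundance is high where targets vanish", {
  tb <- random_log_table(n = 30, p = 8, n_miss = 0, seed = 6)
  m <- as_abund_matrix(tb)
  hits <- 0
  n_seeds <- 300
  for (s in seq_len(n_seeds)) {
    mk <- inject_mar(tb, 0.1, seed = s)
    ev <- attr(mk, "events")
    # pooled over events: driver abundance at masked cells, centered on each
    # event's own driver mean, is positive if masking tracks high drivers
    excess <- 0
    for (e in seq_len(nrow(ev))) {
      cells <- mk[mk$event == e & mk$metabolite_id == ev$target[e], ]
      drv <- m[, ev$driver[e]]
      excess <- excess +
        sum(drv[match(cells$sample_id, rownames(m))] - mean(drv))
    }
    hits <- hits + (excess > 0)
  }
  expect_gte(hits / n_seeds, 0.99)
})

test_that("mixture splits the quota evenly with disjoint sub-masks", {
  tb <- complete_150x60()
  mk <- inject_mixture(tb, 0.12, seed = 7)
  expect_equal(nrow(mk), 1080)
  counts <- table(mk$mechanism)
  expect_equal(unname(counts[c("MCAR", "MAR", "MNAR")]), rep(360L, 3),
               ignore_attr = TRUE)
  # no cell double-masked
  expect_equal(anyDuplicated(mk[, c("sample_id", "metabolite_id")]), 0L)

  # remainder rule: pairwise label counts differ by at most 1 at any rate
  for (rate in c(0.031, 0.052, 0.07)) {
    ct <- table(inject_mixture(tb, rate, seed = 8)$mechanism)
    expect_lte(max(ct) - min(ct), 1)
  }
})

test_that("masks restore losslessly and respect prior missingness", {
  tb <- random_log_table(n = 12, p = 6, n_miss = 8, seed = 7)
  before <- as_abund_matrix(tb)
  for (inj in list(inject_mcar, inject_mar,
                   function(t, r, seed) inject_mnar(t, r, seed),
                   function(t, r, seed) inject_mixture(t, r, seed))) {
    mk <- inj(tb, 0.15, seed = 3)
    # injected cells were all observed in the source
    expect_false(any(is.na(mk$true_value)))
    masked <- apply_mask(tb, mk)
    expect_equal(sum(is.na(as_abund_matrix(masked))),
                 sum(is.na(before)) + nrow(mk))
    expect_identical(as_abund_matrix(restore_mask(masked, mk)), before)
  }
})

test_that("single-cell insertion samples without replacement, deterministically", {
  tb <- random_log_table(n = 10, p = 8, n_miss = 10, seed = 8)
  a <- insert_single_missing(tb, seed = 5)
  b <- insert_single_missing(tb, seed = 5)
  expect_identical(a$position, b$position)
  expect_equal(nrow(a$mask), 1)
  expect_true(all(c("pct_missing", "cv") %in% names(a$position)))

  used <- tibble::tibble(sample_id = character(0), metabolite_id = character(0))
  n_eligible <- sum(!is.na(as_abund_matrix(tb)))
  draws <- 40
  for (i in seq_len(draws)) {
    ins <- insert_single_missing(tb, seed = i, exclude = used)
    used <- rbind(used, ins$position[, c("sample_id", "metabolite_id")])
  }
  expect_equal(anyDuplicated(used), 0L)
  exhaust <- used
  for (i in seq_len(n_eligible - draws)) {
    ins <- insert_single_missing(tb, seed = 1000 + i, exclude = exhaust)
    exhaust <- rbind(exhaust, ins$position[, c("sample_id", "metabolite_id")])
  }
  expect_error(insert_single_missing(tb, seed = 1, exclude = exhaust),
               "No eligible")
})

test_that("missingness filter keeps metabolites at or below the threshold", {
  m <- matrix(1, 10, 3, dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
  m[1:5, "b"] <- NA   # 50%
  m[1:8, "c"] <- NA   # 80%
  tb <- abundance_table(m)
  expect_identical(metabolite_ids(filter_by_missingness(tb, 75)), c("a", "b"))
  expect_identical(metabolite_ids(filter_by_missingness(tb, 100)), c("a", "b", "c"))
  expect_identical(
    metabolite_ids(filter_by_missingness(tb, 0)),
    metabolite_ids(split_complete(tb)$complete)
  )
})
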