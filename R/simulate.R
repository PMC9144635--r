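#' Simulate a technical-replicate peak table
#'
#' Emulates repeated injections of one pooled reference plasma: every sample
#' is a technical replicate, so metabolite `j` is log-normal around a fixed
#' median `10^mu_j` with a per-metabolite analytical CV and no sample-level
#' effects. The CV is imposed exactly through the log-normal relation
#' `sigma_ln = sqrt(ln(1 + CV^2))`. Defaults give a 150 x 60 complete table
#' with log10 medians spanning 3.5-7 and CVs 0.05-0.6.
#'
#' @param n_samples,n_metabolites Table dimensions (>= 2 each).
#' @param log_mean_range Range of per-metabolite log10 medians.
#' @param cv_range Range of per-metabolite target CVs, in (0, 1].
#' @param sample_scale_sd Standard deviation (log10) of an optional per-sample
#'   scaling factor emulating injection-volume drift; 0 (off) by default.
#' @param seed Integer seed; the table is a pure function of the arguments.
#' @return A raw-scale [abundance_table()] with no missing entries. The
#'   generating truth (per-metabolite `log_median` and `target_cv`) is
#'   attached and retrievable with [sim_truth()].
#' @export
simulate_replicates <- function(n_samples = 150, n_metabolites = 60,
                                log_mean_range = c(3.5, 7.0),
                                cv_range = c(0.05, 0.6),
                                sample_scale_sd = 0, seed = 1) {
  stopifnot(n_samples >= 2, n_metabolites >= 2,
            length(cv_range) == 2, cv_range[1] <= cv_range[2],
            cv_range[1] > 0, cv_range[2] <= 1,
            length(log_mean_range) == 2)
  seed <- check_seed(seed)
  withr::with_seed(seed, {
    mu <- stats::runif(n_metabolites, log_mean_range[1], log_mean_range[2])
    cv <- stats::runif(n_metabolites, cv_range[1], cv_range[2])
    s10 <- sqrt(log(1 + cv^2)) / log(10) # log10 sd matching the target CV
    noise <- matrix(stats::rnorm(n_samples * n_metabolites), n_samples)
    logm <- sweep(sweep(noise, 2, s10, `*`), 2, mu, `+`)
    if (sample_scale_sd > 0) {
      logm <- logm + stats::rnorm(n_samples, 0, sample_scale_sd)
    }
  })
  m <- 10^logm
  dimnames(m) <- list(
    sprintf("rep_%03d", seq_len(n_samples)),
    sprintf("met_%03d", seq_len(n_metabolites))
  )
  out <- abundance_table(m, scale = "raw")
  attr(out, "truth") <- tibble(
    metabolite_id = colnames(m), log_median = mu, target_cv = cv
  )
  attr(out, "seed") <- seed
  out
}

#' Simulate a biological cohort peak table with age effects
#'
#' Emulates a cross-sectional primate cohort: each sample has an age drawn
#' uniformly from `age_range` (plus a sex label), and metabolite `j` follows
#' `log10(abundance) = intercept_j + beta_j * age + loadings_j' f + noise`.
#' A fraction `frac_affected` of metabolites get a nonzero slope `beta_j ~
#' Normal(0, effect_sd)`; the rest have `beta_j = 0`. The `f` are `n_factors`
#' standard-normal per-sample latent factors with Normal(0, `factor_sd`)
#' loadings: they create the correlated metabolite modules (shared pathways,
#' extraction and injection covariation) that real peak tables show and that
#' model-based imputers exploit. Noise is log-normal with a per-metabolite CV
#' tied to abundance level: the least abundant metabolites sit at the top of
#' `noise_cv_range` and the most abundant at the bottom (with a small random
#' jitter), mirroring the near-LoD inflation of relative noise that
#' two-component measurement-error behavior produces on real instruments.
#' Raw abundances are always positive. True slopes are recorded and
#' retrievable with [sim_truth()] for parameter-recovery checks.
#'
#' When `baseline_missing_rate > 0` the generator also produces the "full"
#' table dialect through detection-limit censoring, the dominant natural
#' mechanism in GC-MS data: a global limit of detection is placed so that the
#' expected fraction of censored cells equals `baseline_missing_rate`, and a
#' cell goes missing with probability `plogis((lod - log10(x)) / lod_width)`
#' — detection near the limit is stochastic, so low cells are likely (not
#' certain) to drop out. Per-metabolite missingness therefore spans 0-100%
#' and is intrinsically coupled to abundance level and CV — low, noisy
#' metabolites lose the most values, exactly as near-LoD peaks do on an
#' instrument. The realized per-metabolite missing fractions are recorded in
#' the truth table.
#'
#' @param n_samples,n_metabolites Table dimensions.
#' @param age_range Age span in years.
#' @param effect_sd SD of nonzero age slopes, log10 units per year.
#' @param frac_affected Fraction of metabolites with a nonzero slope.
#' @param noise_cv_range Range of per-metabolite residual CVs; the top of the
#'   range applies to the least abundant metabolites, the bottom to the most
#'   abundant.
#' @param n_factors,factor_sd Number of latent covariance factors and the
#'   standard deviation (log10 units) of their metabolite loadings; set
#'   `n_factors = 0` for mutually independent metabolites.
#' @param log_mean_range Range of per-metabolite log10 intercept levels
#'   (abundance at the age-range midpoint).
#' @param baseline_missing_rate Target overall fraction of naturally missing
#'   cells (0 = complete table).
#' @param lod_width Softness of the detection limit, in log10 decades: the
#'   scale of the logistic dropout curve around the LoD.
#' @param seed Integer seed.
#' @return A raw-scale [abundance_table()] with an `age` and `sex` covariate.
#' @export
simulate_biological <- function(n_samples = 45, n_metabolites = 100,
                                age_range = c(6, 23), effect_sd = 0.01,
                                frac_affected = 0.3,
                                noise_cv_range = c(0.1, 0.4),
                                n_factors = 4, factor_sd = 0.15,
                                log_mean_range = c(3.5, 7.0),
                                baseline_missing_rate = 0, lod_width = 0.3,
                                seed = 1) {
  stopifnot(n_samples >= 3, n_metabolites >= 2,
            age_range[1] < age_range[2],
            frac_affected >= 0, frac_affected <= 1,
            baseline_missing_rate >= 0, baseline_missing_rate < 1)
  seed <- check_seed(seed)
  withr::with_seed(seed, {
    age <- stats::runif(n_samples, age_range[1], age_range[2])
    sex <- sample(c("F", "M"), n_samples, replace = TRUE, prob = c(0.75, 0.25))
    level <- stats::runif(n_metabolites, log_mean_range[1], log_mean_range[2])
    affected <- stats::runif(n_metabolites) < frac_affected
    beta <- ifelse(affected, stats::rnorm(n_metabolites, 0, effect_sd), 0)
    # relative noise rises toward the low end of the dynamic range
    rel <- (level - log_mean_range[1]) / max(diff(log_mean_range), 1e-12)
    cv <- noise_cv_range[2] - rel * (noise_cv_range[2] - noise_cv_range[1])
    cv <- pmin(pmax(cv * stats::runif(n_metabolites, 0.85, 1.15),
                    noise_cv_range[1]), noise_cv_range[2])
    s10 <- sqrt(log(1 + cv^2)) / log(10)
    # intercepts anchored at the mid-age so `level` is the typical abundance
    intercept <- level - beta * mean(age_range)
    noise <- matrix(stats::rnorm(n_samples * n_metabolites), n_samples)
    logm <- outer(age, beta) +
      sweep(sweep(noise, 2, s10, `*`), 2, intercept, `+`)
    loadings <- matrix(0, n_metabolites, max(n_factors, 1))
    if (n_factors > 0) {
      factors <- matrix(stats::rnorm(n_samples * n_factors), n_samples)
      loadings <- matrix(stats::rnorm(n_metabolites * n_factors, 0, factor_sd),
                         n_metabolites)
      logm <- logm + factors %*% t(loadings)
    }
    dropped <- matrix(FALSE, n_samples, n_metabolites)
    if (baseline_missing_rate > 0) {
      # place the LoD so the expected dropout equals the target rate
      lod <- stats::uniroot(
        function(l) mean(stats::plogis((l - logm) / lod_width)) -
          baseline_missing_rate,
        interval = range(logm) + c(-10, 10)
      )$root
      dropped <- matrix(
        stats::runif(length(logm)) < stats::plogis((lod - logm) / lod_width),
        n_samples
      )
    }
  })
  m <- 10^logm
  dimnames(m) <- list(
    sprintf("animal_%03d", seq_len(n_samples)),
    sprintf("met_%03d", seq_len(n_metabolites))
  )
  m[dropped] <- NA
  miss_frac <- colMeans(is.na(m))
  cov <- tibble(sample_id = rownames(m), age = age, sex = sex)
  out <- abundance_table(m, scale = "raw", covariates = cov)
  attr(out, "truth") <- tibble(
    metabolite_id = colnames(m), intercept = intercept, beta = beta,
    noise_cv = cv, baseline_missing_frac = miss_frac
  )
  attr(out, "loadings") <- loadings
  attr(out, "seed") <- seed
  out
}

#' Retrieve the generating truth of a simulated table
#'
#' @param table A table produced by [simulate_replicates()] or
#'   [simulate_biological()].
#' @return The per-metabolite truth tibble recorded at generation time.
#' @export
sim_truth <- function(table) {
  tr <- attr(table, "truth")
  if (is.null(tr)) abort("`table` carries no simulation truth.")
  tr
}
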