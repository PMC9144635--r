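---
title: "Benchmarking missing-value imputation for GC-MS peak tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-value imputation for GC-MS peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomiss)
library(dplyr)
```

## The problem

Untargeted GC-MS metabolomics produces wide peak tables — samples by
metabolites — in which a substantial fraction of cells is missing: analytes
fall below the detection limit (missing not at random, MNAR), abundant
co-eluting compounds suppress the detection of others (missing at random,
MAR), and derivatization or ionization failures strike indiscriminately
(missing completely at random, MCAR). Downstream statistics need complete
matrices, so practitioners impute — and every single-imputation method
distorts the data in its own way. `metabomiss` provides the machinery to
measure those distortions under controlled conditions: simulate peak tables
with known truth, inject missingness under each mechanism, impute with ten
standard methods behind one interface, and quantify both cell-level accuracy
(RMSE, percent bias) and the bias imputation induces in downstream statistics
(Cronbach's alpha, per-metabolite regression slopes and p-values).

All analysis happens on the log10 abundance scale, the scale on which peak
intensities are approximately normal; CVs are always reported on the raw
scale, the conventional analytical definition.

## Synthetic data as the test bed

Real reference datasets are instrument- and lab-specific, so the package
ships generators whose outputs have the statistical structure the analyses
assume, with the generating truth recorded and retrievable.

**Technical replicates** (`simulate_replicates()`): every sample is a
repeated injection of one pooled plasma, so metabolite `j` is log-normal
around a fixed median `10^mu_j` with an analytical CV imposed exactly via
`sigma_ln = sqrt(ln(1 + CV^2))`. Defaults — 150 samples, 60 metabolites,
log10 medians uniform on [3.5, 7], CVs uniform on [0.05, 0.6] — give a
complete table spanning the dynamic range and noise levels typical of pooled
QC material. There is no sample-level effect by default (an optional
injection-drift term exists and is off), so metabolites are mutually
independent: the right null structure for asking "how bad can a method be
when there is nothing to learn?", and for the method-ranking experiment,
where determined-value methods (zero, half-minimum) must lose badly to
anything mean-reverting.

**Biological cohorts** (`simulate_biological()`): 45 animals with ages
uniform on [6, 23] years; metabolite `j` follows

    log10(x_ij) = intercept_j + beta_j * age_i + loadings_j' f_i + eps_ij

A 30% fraction of metabolites carries a nonzero age slope,
`beta_j ~ N(0, 0.01)` log10 units per year (about ±0.2 decades across the
age span at one standard deviation — effects detectable but not dominant at
n = 45). The `f_i` are four latent standard-normal factors per sample with
`N(0, 0.15)` loadings; they produce the correlated metabolite modules
(shared pathways, extraction and injection covariation) that real peak
tables always show. This term matters: without it, metabolites are
conditionally independent, model-based imputers have nothing to exploit, and
imputation error cannot degrade with missingness — the factor structure is
what makes the deep-dive experiment meaningful. Residual CVs are uniform on
[0.1, 0.4], biological plus technical noise.

**Natural missingness** for "full"-table experiments is generated by
detection-limit censoring: a global LoD is placed so the expected dropout
matches `baseline_missing_rate`, and each cell drops out with probability
`plogis((lod - log10(x)) / lod_width)` with a default width of 0.3 decades —
detection near the limit is stochastic, not a hard threshold. This couples
per-metabolite missingness to abundance and CV exactly as on an instrument:
low, noisy metabolites lose the most cells, and a table targeted at 30%
overall missingness contains the full 0-100% per-metabolite spectrum. A
first implementation drew per-metabolite missing fractions independently of
abundance; that produced synthetic data in which imputation accuracy did
*not* deteriorate for heavily missing metabolites (their observed values are
a truncated, low-variance tail, so mean-reverting predictions look deceptively
good), which is unrealistic — the LoD model replaced it.

What the generators deliberately do not model: chromatographic drift, batch
structure, non-log-normal heavy tails, metabolite-specific detector
saturation. Passing benchmarks on this synthetic bed therefore demonstrates
that the machinery and the qualitative mechanism-level behavior are right; it
does not certify performance numbers for any particular instrument.

## Injecting missingness

All injectors return a mask (cell positions, mechanism labels, true values)
rather than a mutated table, so any experiment can be unwound exactly.
Counts use round-half-away-from-zero; the realized rate is always recorded
next to the target rate.

* **MCAR** removes `round(rate * n_observed)` cells uniformly without
  replacement.
* **MNAR** repeatedly picks a metabolite at random, draws a percentage from
  a chi-squared distribution (df = 6 by default: right-skewed, mean 6%),
  and masks that metabolite's lowest observed values. Draws accumulate, per
  metabolite, up to a cap of 80% of its observed cells; the final draw is
  truncated (lowest cells kept masked) so the global count is exact.
  Metabolite selection is with replacement — without it, global rates beyond
  the mean chi-squared draw would be unreachable, and the supported range
  must span 2-70%. Ties among equal lowest values break by sample index.
* **MAR** repeatedly picks a (driver, target) pair, draws a removal
  percentage uniformly from 5-50%, and masks the target's cells in the
  samples where the driver is most abundant — the co-elution suppression
  story. Per-event driver/target provenance is kept for verification.
* **Mixture** applies MCAR, then MAR, then MNAR, each restricted to
  still-observed cells, at equal thirds of the global quota (remainder in
  that fixed order, so label counts differ pairwise by at most one).

The chi-squared df, the MAR percentage range, and the MNAR cap are exposed
as arguments because no canonical values exist; the defaults are the
package's documented choices.

## The ten imputers

`impute(table, method)` dispatches to ten single-imputation methods with
registry defaults (`imputation_methods()`). Two hard invariants hold for
every method and are tested on every fixture: observed cells are returned
bit-identical, and complete tables pass through unchanged.

Determined-value methods: **zero** (0 on the current scale), **half
minimum** (LoD surrogate: half the metabolite's minimum, i.e.
`min - log10(2)` on the log scale), **mean**. Neighbor methods: **kNN**
(Euclidean distance over co-observed samples, normalized by co-observation
count; 1/distance-weighted neighbor average; k = 10) and **LLS** (ordinary
least squares of the target on its k = 10 most correlated neighbors, with a
recorded mean fallback for rank-deficient designs). Low-rank methods:
**SVD** (alternating truncated-rank-5 reconstruction) and **BPCA**
(variational Bayesian PCA in the style of Oba and colleagues: per-sample
latent posteriors computed from observed coordinates only, automatic
relevance determination pruning superfluous components; written in-package
because no installed library provides it). Chained-regression methods:
**RF** (missForest-style iteration on ranger forests, 100 trees, stopping at
the first increase in imputed-value change and returning the previous pass),
**GRR** (ridge regression via glmnet, per-metabolite penalty chosen by
internal 5-fold cross-validation over a 25-point log-spaced grid; a
closed-form standardized ridge handles the single-predictor case glmnet
rejects, and tables with fewer than 8 observed values for a metabolite skip
the CV), and **QR** (linear quantile regression at the median by iteratively
reweighted least squares on the pinball loss with a small ridge — written
in-package, with recorded mean fallbacks for degenerate designs).

Every iterative method initializes from the metabolite-mean fill, making
runs deterministic given the seed. Hyperparameter defaults are the package's
own reasoned choices, all overridable per call or through the benchmark
drivers' `method_params`.

## Measuring accuracy and downstream bias

`rmse()` and `percent_bias()` are computed strictly over masked cells —
perturbing anything outside the mask cannot change them. RMSE is evaluated
on the log10 analysis scale; the in-depth experiment reports percent bias on
the raw scale (back-transformed), where it reads as a relative concentration
error.

Downstream bias has three probes. `cronbach_alpha()` with an explicit items
axis (samples for replicate-style consistency, metabolites for
metabolite-correlation analyses — never inferred). `regression_bias()` fits
`abundance ~ age` per metabolite on true and imputed tables; the sign
conventions are chosen so that a negative mean `abs_beta_diff`
(`|beta_imputed| - |beta_true|`) reads "imputation shrinks effect sizes" and
a positive mean `p_diff` (`p_imputed - p_true`) reads "p-values become less
significant". Both the raw and magnitude coefficient differences are
reported, since shrinkage is a statement about magnitudes. Departures from
zero use one-sample t-tests, methods are compared with unpaired Wilcoxon
rank-sum tests (midranks for ties, exact null for small tie-free groups),
and p-value families are Benjamini-Hochberg adjusted.

## The four experiment drivers

Each driver is a pure function of (data, config, seed): per-cell sub-seeds
come from one splitter (`derive_seeds()`), failures abort only their own
cell and are logged in the report, and a truth-passthrough `"oracle"`
pseudo-method is accepted everywhere — wiring it through any experiment must
yield exactly zero error, which validates the plumbing independently of any
imputer.

`run_accuracy_benchmark()` shares one injected mask across all methods per
cell, so method comparisons are paired; per-metabolite records carry
raw-scale CV bins (breaks at 0.1/0.2/0.3) and injected-missingness bins for
the RMSE-on-CV and RMSE-on-missingness regressions. The default rate grid
spans 2-70% and the mixture mechanism is the headline condition, since all
three mechanisms co-occur in real data. `run_consistency_assessment()` and
`run_regression_bias_assessment()` default to 10% and 20% global rates.
`run_indepth_single_value()` implements the deep dive: filter metabolites
above 75% missing, then repeatedly mask one observed cell (sampling without
replacement), impute the whole table, and record only that cell's error with
its host metabolite's missingness and CV; an optional sweep re-runs the
alpha/regression probes at 10-70% overall missingness.

`write_report()` emits the full file contract (records, per-metabolite,
consistency, regression, summary CSVs plus tests and provenance JSON) with
header-only files for empty sections, and the provenance block is sufficient
to re-run a report identically.

## Numerical choices and edge cases

* Convergence for SVD/BPCA/GRR/QR is the maximum relative change in imputed
  cells (normalized by the table's largest magnitude) falling below `tol`;
  non-convergence is reported via `converged = FALSE`, never an error.
* The RF stopping rule is the first increase of the summed squared change;
  oscillation is bounded by `max_iter`.
* Undefined CVs (fewer than 2 observations, non-positive mean) are flagged,
  not coerced to zero. Zeros on the raw scale are rejected as scale errors
  rather than treated as missing; the missing-sentinel set for file input is
  configurable and excludes `"0"` by default.
* Constant vectors are excluded (with a warning) from pairwise correlation;
  zero-variance inputs to alpha or the t-test error out loudly.
* Injected masks never target an already-missing cell, and unwinding a mask
  restores the source table bit-for-bit.

## Problem sizes

The shipped test suite and the acceptance script run desk-scale versions of
the four experiments: the 150 x 60 replicate table with 20 repeats at 10%
mixture missingness for method ranking; 45 x 100 biological tables at 10%
and 20% for the bias and consistency probes (5 repeats each); and a 45 x 150
full table at 30% LoD censoring with 250 single-cell insertions (single-pass
30-tree forests) for the deep dive. A wide table matters in the deep dive:
its missingness bins are populated by metabolites, not by insertions, so a
narrow table makes the binned medians idiosyncratic. These sizes reproduce
the qualitative findings stably under a fixed seed; scaling any of them up
is a matter of changing the driver arguments.

## Known limitations

Single imputation only — multiple imputation with pooled inference is out of
scope by design. One qualitative real-data pattern does not transfer to this
synthetic bed: on log10 tables whose between-metabolite spread dwarfs the
noise, Cronbach's alpha over sample items is compressed against 1 and all
model-based imputers nudge it upward by a similar hair, ordered by how
strongly they revert to the metabolite mean; on a Gaussian factor bed BPCA
is correctly specified and so cannot over-smooth relative to RF or ridge
the way it can on real instrument data. Method-vs-method consistency
contrasts measured here should therefore be read as properties of this bed,
not forecasts for a given instrument. The generators' assumptions (log-normality, linear age
effects, Gaussian factor modules, logistic LoD) are idealizations; mechanism
diagnosis on real data is a separate, unsolved problem, and nothing here
infers which mechanism produced a real table's gaps. BPCA's ARD behavior on
tables with many more metabolites than samples depends on initialization
scale; the SVD-based deterministic start makes results reproducible but is
not guaranteed to find the global variational optimum.
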