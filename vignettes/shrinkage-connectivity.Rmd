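---
title: "Shrinkage prediction of test–retest connectivity maps: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shrinkage prediction of test–retest connectivity maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcshrink)
```

## The prediction problem

A seed-based connectivity map summarizes, for every voxel of a region of
interest, how strongly that voxel's resting-state BOLD series co-fluctuates
with the region's average (seed) signal. Maps computed from short scans are
noisy: with T time points, even a perfectly stable underlying correlation is
measured with Fisher-scale sampling variance of about 1/(T−3), and real
scan–rescan data add genuine session-to-session variability on top. Given
two-session data, this package asks how well the *second* session's map of
each subject can be predicted from *first*-session data alone, and shows
that a reliability-weighted compromise between the subject's own map and the
group-average map predicts best.

## Model and estimators

All estimation happens on the Fisher-Z scale, where correlations are
approximately normal with stabilized variance. Writing `V_ij(v)` for the
Fisher-transformed correlation of subject `i`, session `j`, voxel `v`, the
measurement-error model is

$$V_{ij}(v) = X_i(v) + U_{ij}(v),$$

with true subject-level connectivity `X_i(v)` (mean `mu_x(v)`, between-subject
variance `sigma2_x`) and independent session error `U_ij(v)` (mean 0,
variance `sigma2_u`). Three predictors of `V_i2(v)` are compared:

* **raw** — the subject's own session-1 value, `V_i1(v)`; unbiased for
  `X_i(v)` but carries the full error variance;
* **mean** — the across-subject session-1 average; nearly noise-free but
  biased for any subject who differs from the population;
* **shrinkage** — the convex combination
  `lambda(v) * mean + (1 - lambda(v)) * raw`, the best linear unbiased
  predictor of `X_i(v)` under the model.

The weight is the noise fraction of the single-measurement variance,

$$\lambda(v) = \frac{\mathrm{Var}\{U(v)\}}{\mathrm{Var}\{X(v)\} + \mathrm{Var}\{U(v)\}} = 1 - \mathrm{ICC}(v),$$

so `lambda` is exactly one minus the voxel's test–retest intraclass
correlation. The two limits behave as reliability intuition demands: a voxel
measured without error (`Var{U} = 0`) keeps the subject's own value
(`lambda = 0`), and a voxel whose between-subject signal vanishes
(`Var{X} = 0`) collapses to the group mean (`lambda = 1`). We note that one
published statement of the weight appears with the numerator and the
limiting cases interchanged; this package follows the orientation that
satisfies both limits and the BLUP property, and reports the ICC alongside
as `1 - lambda`. A fixed constant weight (conventionally 0.1, close to the
average voxel reliability reported in scan–rescan studies) can be imposed
instead of the estimated map.

### Variance-component estimation

With two sessions, the session difference `D_i(v) = V_i2(v) - V_i1(v)` has
variance `2 * Var{U}`, giving the moment estimator
`Var{U}(v) = (1/2) * sample-variance_i(D_i(v))`. For the total
single-measurement variance we use the within-session between-subject sample
variance pooled over sessions,

$$\widehat{\mathrm{Var}}\{V\}(v) = \frac{1}{J}\sum_j \frac{1}{I-1}\sum_i (V_{ij}(v) - \bar V_j(v))^2,$$

whose expectation under the model is `Var{X} + Var{U}`, so
`Var{X} = Var{V} - Var{U}` is coherent. (The corresponding printed formula
in the source literature is typographically garbled — a missing square and a
`1/(J(J-1))` prefactor — so the standard moment estimator is used.) A
negative `Var{X}` estimate is a routine finite-sample artifact and is
clamped to zero, which drives `lambda` to 1 at that voxel; clamped voxels
are flagged in the output. When both components are zero (e.g. constant
panels) `lambda = 1` by convention: the raw map then carries no information
beyond the common value, and this choice keeps degenerate inputs exact and
warning-free.

### Degenerate and missing voxels

A zero-variance voxel series (or seed) yields an `NaN` correlation with a
warning; `NaN` propagates through the Fisher transform and predictors and is
excluded voxelwise from group means, variance components, and MSE averages —
the only convention that cannot silently bias `lambda(v)`. A voxel with
fewer than two complete subjects cannot support component estimation and
receives the fixed fallback weight (default 0.1). Correlations are clipped
to `|W| <= 1 - 1e-7` before `artanh` so Fisher values stay finite while
perturbing genuine correlations by less than `1e-7`; all arithmetic is in
double precision.

## Evaluation

Each predictor is scored per subject by the mean squared error against the
observed session-2 map over the voxels that are non-`NaN` in both. The MSE
can be computed on the correlation scale or on the Fisher scale; the
package computes both and defaults to Fisher, matching how headline results
in the test–retest literature are described. Percent reduction relative to
raw is `100 * (mse_raw - mse_other) / mse_raw`, kept unrounded internally
and rounded to two decimals only in display columns. The summary block
reports per-method mean, median (midpoint of the two central values for
even counts), extremes, and Tukey boxplot outliers with quartiles taken as
medians of the lower/upper halves of the sorted values, the overall median
excluded when the count is odd — the convention fixed so the outlier count
is deterministic.

## The synthetic-data generators

Two generators provide ground truth for every downstream stage.

**Model-level** (`generate_fisher_panel()`) draws `X_i(v)` and `U_ij(v)`
directly on the Fisher scale. Its defaults mirror a small two-session
resting-state study: J = 2 sessions, T = 74 time points, `sigma2_x = 0.04`
and `sigma2_u = 0.01` (Fisher-Z² units) — variances of a size typical for
seed-based maps, giving a generative weight `lambda = 0.2` and ICC 0.8.

**Time-series level** (`generate_timeseries_panel()`) synthesizes BOLD-like
signals so the correlation and seed-course code paths are exercised: per
scan, a latent standard-normal seed signal `s(t)` and per-voxel series
`y(v,t) = rho * s(t) + sqrt(1 - rho^2) * eps(v,t)`, with
`rho_ij(v) = tanh(X_i(v) + B_ij(v))` and the session effect `B_ij(v)` added
on the Fisher scale *before* `tanh` so the measurement-error model stays
exactly additive on the analysis scale. Signals are white by default — the
source literature specifies no temporal noise model, and whiteness keeps the
Fisher sampling variance exactly `1/(T-3)`; an optional AR(1) coefficient
(default 0) is exposed for sensitivity analyses. True correlations are
clipped to `|rho| <= 0.999` before synthesis to avoid degenerate series. The
effective error variance on the Fisher scale is approximately
`sigma2_u + 1/(T-3)`, which `true_lambda(..., mode = "timeseries")`
accounts for. One master seed drives a deterministic per-(subject, session)
substream, so panels are bit-reproducible regardless of generation order.

What the generators deliberately do **not** emulate: motion, drift,
physiological noise, spatial autocorrelation, and anatomical structure.
Passing tests therefore demonstrate correctness of the estimation machinery
under the stated model, not robustness to fMRI artifacts — on real data,
preprocessing quality and mask choice will dominate.

The latent seed signal is returned in the ground truth so that calibration
checks (e.g. the `1/(T-3)` sampling variance) can correlate voxels against
the true seed rather than the mask-average seed, which contains each voxel's
own noise; the analysis pipeline itself always uses the mask-average seed,
including the target voxel, with no self-exclusion — the seed is defined as
the plain ROI average, and the induced self-correlation inflation is part of
that definition.

## Numerical and design choices

* **Voxel enumeration** is fixed ascending by x, then y, then z (0-based
  indices in reports), identical across mask loading, panel loading, and
  map writing; affine/world coordinates ride along in headers but never
  enter computation. Grid mismatches are errors, not resampling triggers.
* **Mask threshold** is strictly `> 0.5`, accommodating binary and
  probabilistic/resampled masks alike.
* **Background voxels** of output maps are `NaN`, not 0, so genuine zero
  correlations remain distinguishable.
* **Estimation circularity**: as in the source analyses, `lambda(v)` is
  estimated from both sessions of the same data being evaluated; a
  precomputed `lambda_map` can be supplied to `shrink()` to break that
  circularity in methodological experiments.
* **Problem sizes**: calibration checks use I = 200 subjects × 500 voxels
  for λ recovery (tolerance 0.03), 10,000 scan-voxel cells at T = 74 for
  the sampling-variance check (tolerance 10%), and I = 50 × V = 2000 for
  the MSE closed forms (tolerance 10%) — sizes at which Monte-Carlo error
  is comfortably inside those tolerances while a full run completes in
  seconds.
* **Reference arithmetic**: the package ships a published 21-subject
  per-subject MSE table (plain text) and reproduces its summary statistics
  — extremes, Tukey outliers, percent reductions recomputed from the
  reported averages. The reported per-subject values are rounded to four
  decimals, so column means differ from the reported average row in the
  fourth decimal and recomputed percentages can differ by a few hundredths
  of a point; comparisons allow that rounding slack.

## A complete run

```{r pipeline, eval = FALSE}
out <- file.path(tempdir(), "demo")
run_pipeline(list(mode = "run-all", out_dir = out, seed = 7,
                  synth_n_subjects = 10, synth_n_voxels = 200,
                  synth_n_timepoints = 74))
read.delim(file.path(out, "evaluate", "mse_table.tsv"))
```

The run directory contains the simulated NIfTI scans with their manifest
and mask, the fitted Fisher panel, voxelwise variance components and
λ/ICC, the three prediction sets, the per-subject MSE table with display
columns, the summary table, the resolved configuration, and a log of
per-stage record counts. Repeating the call with the same seed reproduces
every table byte for byte.

## Known limitations

* Variance components require exactly two sessions (the replication design
  the session-difference estimator is built for); panels with more sessions
  can be generated but are refused by `variance_components()` rather than
  silently subset.
* `lambda(v)` is estimated independently per voxel with no spatial
  smoothing or regularization; in small samples the voxelwise estimates are
  noisy, and the fixed-weight option is the pragmatic alternative.
* Real-data use assumes fully preprocessed, registered, equal-length scans;
  the package performs no registration, filtering, or nuisance regression.
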