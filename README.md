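# fcshrink

Shrinkage prediction of test–retest functional connectivity maps from
resting-state fMRI.

## The problem

In scan–rescan resting-state fMRI, a subject's seed-based connectivity map
estimated from one short session is a noisy measurement of that subject's
true connectivity: session-to-session variability and the sampling error of
correlations computed from a few dozen time points both contribute. Given
only session-1 data, how should we predict the session-2 map of the same
subject? The subject's own session-1 map (the *raw* predictor) is unbiased
but noisy; the across-subject average map (the *mean* predictor) is stable
but ignores individual differences. `fcshrink` implements the classical
compromise: an empirical-Bayes *shrinkage* predictor that pulls each
subject's map toward the group mean by an amount determined by the voxel's
measured test–retest reliability.

## The model

For subject *i*, session *j*, and ROI voxel *v*, the seed time course is the
unweighted voxel average `Y_ij^S(t) = |S|^{-1} Σ_{v∈S} Y_ij(v,t)`, the
connectivity map `W_ij(v)` is the Pearson correlation of each voxel's series
with the seed, and `V_ij(v) = artanh(W_ij(v))` is its Fisher-Z transform.
On that variance-stabilized scale a classical measurement-error model is
assumed:

    V_ij(v) = X_i(v) + U_ij(v),   X_i(v) ~ (μ_x(v), σ²_x),  U_ij(v) ~ (0, σ²_u)

with `X_i(v)` the subject's true connectivity and `U_ij(v)` independent
session-level error. The best linear unbiased predictor of `X_i(v)` given
one replicate is the convex combination

    V̂_i2^SH(v) = λ(v) · V̂_2^M(v) + (1 − λ(v)) · V̂_i2^R(v)

where `V̂_i2^R = V_i1` (raw), `V̂_2^M = mean_i V_i1` (group mean), and the
shrinkage weight is the noise fraction of the total variance,

    λ(v) = Var{U(v)} / (Var{X(v)} + Var{U(v)}) = 1 − ICC(v).

A perfectly reliable voxel (ICC = 1) keeps the subject's own value
(λ = 0); a fully unreliable voxel collapses to the group mean (λ = 1).
Variance components are estimated voxelwise from the two sessions:
`Var{U}` from half the between-subject variance of the session differences
`D_i(v) = V_i2(v) − V_i1(v)`, `Var{V}` as the within-session between-subject
variance pooled over sessions, and `Var{X} = max(Var{V} − Var{U}, 0)`.
Predictions are back-transformed with `tanh` and scored against the observed
session-2 maps by the per-subject mean squared error over ROI voxels.

## Worked example

Simulate a 20-subject, two-session panel directly on the Fisher-Z scale
with known variances (σ²_x = 0.04 between subjects, σ²_u = 0.01 session
noise, so the generative weight is λ = 0.01/0.05 = 0.2), estimate λ(v),
and score the three predictors:

```r
library(fcshrink)

sim <- generate_fisher_panel(synth_config(n_subjects = 20, n_voxels = 300,
                                          sigma2_x = 0.04, sigma2_u = 0.01,
                                          rng_seed = 42))
vc  <- variance_components(sim$panel)
lam <- lambda_map(vc)
cat("mean estimated lambda:", round(mean(lam$lambda), 3),
    "| generative value:", sim$truth$lambda_true, "\n")
#> mean estimated lambda: 0.222 | generative value: 0.2

tab <- evaluation_table(sim$panel)          # Fisher-scale MSE per subject
tab[-1] <- round(tab[-1], 4)
head(tab, 4)
#>   subject mse_raw mse_mean red_mean_pct mse_shrinkage red_shrink_pct
#> 1   sub01  0.0222   0.0419     -88.7550        0.0183        17.4492
#> 2   sub02  0.0184   0.0410    -122.8895        0.0169         8.1139
#> 3   sub03  0.0181   0.0430    -136.9598        0.0160        11.9355
#> 4   sub04  0.0209   0.0474    -127.2234        0.0179        14.0536

round(summarize_evaluation(tab)$reductions, 2)
#>      mean shrinkage
#>   -133.94     12.37
```

With these variances the subjects differ substantially, so the group-mean
predictor is far *worse* than raw (negative reduction), yet the shrinkage
predictor — weighting the mean by only λ ≈ 0.2 — still improves on raw for
every subject. In regimes with large session-to-session variability
(λ closer to 1) the reductions grow much larger.

The same analysis runs end to end from NIfTI files: `load_mask()` +
`load_panel()` read a TSV manifest of per-session 4-D volumes,
`connectivity_panel()` produces the correlation and Fisher maps, and
`run_pipeline()` wires simulate → fit → evaluate into a seeded,
byte-reproducible run directory (`mse_table.tsv`, `summary.tsv`, λ/ICC and
prediction maps as NIfTI). A thin command-line front end is installed at
`inst/cli/fcshrink.R` with subcommands `simulate`, `fit`, `evaluate`, and
`run-all`.

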