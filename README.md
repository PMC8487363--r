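# trajcast

Weighted gradient-offset forecasting of longitudinal biomarker
trajectories, and nested cross-validated classification of the completed
trajectories.

## What problem this solves

Short clinical follow-up studies record a panel of markers — cognitive test
scores, MRI-derived regional volumes and thicknesses — at a few equally
spaced visits, and ask whether a subject with mild cognitive impairment
(MCI) will progress to dementia or remain stable. `trajcast` is for
researchers who want to (a) forecast the next visit's marker values from
the two previous ones, and (b) use the completed three-visit trajectories
to separate progressors (MCIp) from stables (MCIs), with honest nested
cross-validation around every learned component.

## The model

Progression is assumed piecewise linear over the follow-up window. With
visits at `t`, `t+Δt`, `t+2Δt` and markers scaled to `(0, 1]` by their
cohort maximum:

* the **base gradient** `δ_m^c(Δt)` is the class-average annual change of
  marker `m` over the first interval;
* a subject's **gradient offset** `OS_m = δ_m^c − δ_m(subject)` is its
  deviation from that typical change, and `fOS_m` is the same deviation on
  the next interval;
* stacking training subjects gives, per marker, `A μ_m = B_m`, solved by
  least squares (`μ_m = (AᵀA)⁻¹AᵀB_m`, minimum-norm SVD form when the
  normal equations are singular) and averaged over leave-one-out folds —
  the `N × N` matrix `μ` says how every marker's current deviation feeds
  every marker's next deviation;
* for a new subject, a linear SVM on the known visits suggests the base
  group, `α_m` is that group's base gradient, and the forecast is
  `ŷ_m(t+2Δt) = y_m(t+Δt) + (α_m + β_m)·Δt` where `β_m` is the
  weighted-offset correction `−Σ_k μ[k,m]·OS_k`;
* completed trajectories feed a second linear SVM whose signed margin
  scores give ROC/AUC; a **ground-truth mode** classifies fully observed
  trajectories as the benchmark ceiling.

Marker panels are grown incrementally by ascending baseline *t*-test
p-value, and every learned component is refit inside each of 5 stratified
outer folds. Real MCI cohorts sit behind controlled access, so the package
includes a synthetic cohort generator with exactly this generative
structure (known coupling matrix = ground-truth `μ`), used by the test
suite for parameter-recovery and benchmarking checks.

## Worked example

Recover a known coupling structure, then run the full pipeline:

```r
library(trajcast)

coupling <- matrix(c(0.25, 0.4, 0,  0, 0.25, 0.4,  0, 0, 0.25), 3, 3)
spec <- cohort_spec(n_progressor = 49, n_stable = 70, n_markers = 3,
                    dt = 0.5,
                    slope_progressor = rep(-0.3, 3),
                    slope_stable = rep(-0.1, 3),
                    coupling_matrix = coupling,
                    subject_slope_sd = 0.2, noise_sd = 0.01,
                    baseline_ranges = cbind(rep(2, 3), rep(4, 3)),
                    seed = 42)
cohort <- generate_cohort(spec)
cohort
#> Longitudinal dataset: 119 subjects (49 progressor / 70 stable), 3 markers, 3 visits, dt = 0.5 y

model <- fit_weights_loo(cohort)
summary(model)
#> Weighted gradient-offset model (dt = 0.5 y, 119 LOO folds)
#>
#> Base gradients (units/yr):
#>   marker01 marker02 marker03
#> 0 -0.09876  -0.1023 -0.09859
#> 1 -0.30260  -0.3045 -0.30000
#>
#> Linear-prediction weights mu (column m predicts marker m):
#>          marker01  marker02  marker03
#> marker01  0.24300 -0.007297 -0.009848
#> marker02  0.39970  0.244400 -0.003871
#> marker03 -0.01719  0.420700  0.252400

max(abs(coef(model) - coupling))
#> [1] 0.02072464
```

The stable class declines at its nominal 0.1/yr and the progressors at
0.3/yr; with 1 % measurement noise the LOO-averaged weights reproduce the
generator's coupling matrix to ~0.02 per element (and exactly, to machine
precision, when `noise_sd = 0`).

The full nested evaluation on the default study-sized cohort
(49 progressors / 70 stables, 10 markers on heterogeneous scales, 6-month
visits):

```r
study <- generate_cohort(cohort_spec(seed = 42))
res <- run_nested_cv(study, run_config(seed = 1))
res
#> Nested CV report: 5-fold outer loop, subset sizes 1..10, modes: forecast, gt
#> Best model (fold-averaged forecast AUC): subset size 10, AUC = 0.8759, MAE = 0.924%

print(aggregate_report(res, "forecast")[c(1, 5, 10), ], digits = 3)
#>        mode subset_size fold mae_percent   auc accuracy sensitivity specificity
#> 1  forecast           1    0       1.807 0.695    0.588       0.184       0.871
#> 5  forecast           5    0       1.301 0.756    0.723       0.529       0.857
#> 10 forecast          10    0       0.924 0.876    0.799       0.693       0.871
#>      n auc_pooled
#> 1  119      0.654
#> 5  119      0.731
#> 10 119      0.866
```

Reading the numbers: third-visit forecasts are off by about 0.9 % of each
marker's normalized range at the full panel, and classification improves
steadily as ranked markers are added (fold-averaged AUC 0.70 → 0.88), the
expected behaviour when every marker carries class signal. `plot(res)`
draws the MAE and AUC trends against subset size;
`select_best_model(res)` returns the best-AUC panel size.

A thin CLI over the same functions lives at `inst/cli/trajcast.R`
(subcommands `simulate`, `rank`, `fit`, `forecast`, `run`).

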