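---
title: "Forecasting longitudinal biomarker trajectories with weighted gradient offsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting longitudinal biomarker trajectories with weighted gradient offsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(trajcast)
```

## The problem

In slowly progressing diseases such as Alzheimer's, subjects with mild
cognitive impairment (MCI) split into *progressors* (who convert to dementia
within follow-up) and *stables* (who retain the MCI diagnosis).  Clinical
cohorts record a panel of markers — cognitive test scores and MRI-derived
regional morphometry — at regular follow-up visits.  Two questions arise:
given a subject's first two visits, what will the next reading be?  And once
the three-visit trajectory is completed (observed or forecast), can it
separate progressors from stables?

`trajcast` implements a linear-prediction answer to both.  It assumes
piecewise-linear progression over the short follow-up window and treats each
subject's *deviation* from its group's typical rate of change as the
informative signal that propagates from one follow-up interval to the next.

## The model

Let $x_{mi}(t)$ be marker $m$ of subject $i$ at visit time $t$, with visits
at $t$, $t+\Delta t$, $t+2\Delta t$.  All markers are first scaled by their
cohort-wide maximum so that heterogeneous scales (test scores vs volumes in
mm³) become comparable.

**Base gradients.** For each class $c \in \{\text{stable},
\text{progressor}\}$ and marker $m$, the base gradient
$$\delta_m^c(\Delta t) = \frac{1}{n_c}\sum_{i \in c}
\frac{x_{mi}(t+\Delta t)-x_{mi}(t)}{\Delta t}$$
is the class-average annual change over the first interval.

**Gradient offsets.** A subject's offset is the base gradient minus its own
observed gradient, $OS_{mi} = \delta_m^c - \delta_{mi}$, computed on the
first interval; the *future* offset $fOS_{mi}$ is the same construction on
the second interval.  Offsets measure how far a subject deviates from its
group's typical trajectory.

**Linear-prediction weights.** Stacking the $n$ training subjects gives, per
marker $m$, an over-determined system
$$A\,\mu_{\cdot m} = B_m, \qquad
A_{ik} = OS_{ki}(\Delta t),\quad B_{mi} = fOS_{mi}(\Delta t),$$
whose least-squares solution
$\mu_{\cdot m} = (A^{\mathsf T}A)^{-1}A^{\mathsf T}B_m$ quantifies how every
marker's current deviation feeds marker $m$'s next deviation.  The $N$
columns form the $N \times N$ weight matrix $\mu$.  Weights are estimated on
each leave-one-out (LOO) fold of the training set and averaged element-wise.

**Forecasting.** For a test subject $y$ with two known visits, a linear SVM
trained on the known time-point values and their annual change suggests the
base group; the suggested class's base gradient becomes $\alpha_m$.  The
subject's offsets $OS_{y m} = \alpha_m - \delta_{y m}$ are pushed through
the weights to a predicted future offset
$\widehat{fOS}_m = \sum_k \mu_{km} OS_{y k}$, and the forecast is
$$\hat y_m(t+2\Delta t) = y_m(t+\Delta t) + \omega_m \Delta t, \qquad
\omega_m = \alpha_m - \widehat{fOS}_m.$$
Because offsets are defined as *base minus gradient*, the predicted future
offset must be subtracted from the base gradient: a subject predicted to
keep lagging its group keeps lagging it.  Writing
$\beta_m = -\widehat{fOS}_m$ recovers the additive form
$\omega_m = \alpha_m + \beta_m$, and in the exactly-coupled noiseless limit
this forecaster reproduces the generative trajectory to machine precision —
a property the test suite checks end to end.  With $\mu = 0$ the forecaster
collapses to class-conditional linear extrapolation with the base gradient.

**Classification.** Completed trajectories (three values per marker,
concatenated over the marker subset) feed a second linear SVM that labels
subjects progressor vs stable and emits signed margin distances used as ROC
scores.  A *ground-truth* (GT) mode classifies fully observed trajectories,
bypassing forecasting; it is the benchmark ceiling any forecast-based
pipeline should approach.

## The evaluation loop

`run_nested_cv()` reproduces the full nested design: markers are ranked by
a two-sample pooled-variance Student's *t*-test on baseline readings, and
nested subsets grow by one marker per rank.  For each subset size and each
of 5 class-stratified outer folds, the weight matrix (inner LOO loop), the
base-group SVM and the trajectory SVM are fitted on the training fold only,
and metrics — forecast MAE (×100 on the normalized scale), rank-statistic
AUC, accuracy, sensitivity (progressor recall), specificity — are recorded
on the held-out fold.  Fold-averaged rows carry the headline numbers; the
fold-pooled AUC is emitted alongside since either convention appears in
practice.  `select_best_model()` picks the subset size with maximal
fold-averaged forecast AUC, ties resolving to the smaller panel.

## Design choices

Several points were genuinely open; the package resolves them as follows.

* **Normalization scope.**  Scaling by the cohort-wide maximum *before* the
  train-test split is the method's own convention and the default, although
  it leaks a trivial statistic (a per-marker maximum) across the split;
  `normalization = "within_train"` applies training-fold maxima to the test
  fold for a leakage-free variant.
* **Student, not Welch.**  Ranking uses the classic pooled-variance
  *t*-test; Welch is available behind `ttest = "welch"`.  Degenerate markers
  (zero pooled variance) rank last when means agree (`p = 1`) and first when
  they differ (`p = 0`), with a warning either way.
* **Ranking scope.**  Markers are ranked once on the full dataset, before
  the outer loop, matching a wrapper-style selection that precedes
  cross-validation.  (Fold-wise re-ranking would change the subsets per fold
  and make subset sizes incomparable across folds.)
* **One pooled weight system.**  $\mu$ is estimated from all training
  subjects jointly, not per class: the stacked system makes no class
  distinction beyond each subject using its own class's base gradient.
* **Base gradients in the LOO loop.**  By default the LOO loop holds base
  gradients fixed at their full-training-set values and only the offset rows
  change per fold (`recompute_base = TRUE` re-estimates them per fold).
  Removing one subject necessarily shifts its class's mean gradient, so
  per-fold re-estimation injects a class-constant artefact of order
  $1/(n_c-1)$ into every offset row; with fixed base gradients the LOO
  average recovers a known coupling matrix exactly in the noiseless limit,
  which is the behaviour a linear-prediction estimator should have.
* **Minimum-norm least squares.**  The weights are computed from the SVD
  with singular values below `max(dim(A)) * eps * max(d)` treated as zero.
  When $A^{\mathsf T}A$ is invertible this equals the normal-equations
  formula; when the system is rank-deficient — more markers than training
  subjects (249 MRI markers vs ~95 subjects in the motivating application),
  or collinear offsets — the minimum-norm solution is returned with a
  warning rather than an error.
* **True labels in training, suggested labels at test time.**  Training
  subjects' offsets use their known class's base gradient; only test
  subjects go through the base-group SVM, which is refit inside every outer
  fold on that fold's training data.
* **ROC scores.**  "Likelihood values" are implemented as signed
  decision-function distances; AUC is rank-based, so any monotone score
  works.  Both SVMs use a linear kernel with $C = 1$ (configurable via
  `svm_c`), without internal feature rescaling since trajectories are
  already normalized.

## The synthetic cohort generator

Real MCI cohort data sit behind controlled access, so the package ships a
generator, `cohort_spec()` / `generate_cohort()`, that emulates exactly the
structure the method assumes — it is a test harness, not a claim about any
real cohort's data-generating process.  Per subject: a uniform baseline per
marker, a subject slope drawn around the class rate, a second-interval slope
whose deviation from the class rate is a known linear map (the coupling
matrix, in the same column convention as $\mu$) of the realized
first-interval deviations of all markers, and additive Gaussian measurement
noise on the readings.  Noise on readings rather than slopes keeps the
latent trajectory piecewise-linear, so the coupling matrix is the exact
ground truth the weight regression should recover.  Subject slopes are
re-centred within class so the empirical class-mean rate equals the nominal
rate exactly; nominal parameters are then exact finite-sample class means
and parameter-recovery checks are sharp rather than $O(n^{-1/2})$-blurred.

Defaults describe the study conditions the package targets: 49 progressors
and 70 stables at $\Delta t = 0.5$ y (the 6-month design; pass `dt = 1` and
35/50 subjects for the annual design), 10 markers on log-spaced scales from
1 to 100 standing in for the mix of cognitive scores and regional volumes,
stable decline of 2 %/yr of scale vs progressor decline of 8 %/yr,
between-subject slope spread of 2 % and measurement noise of 1 % of scale,
and zero cross-marker coupling unless a coupling matrix is supplied.

What the generator does **not** emulate: missing visits and dropout,
floor/ceiling effects of test scores, non-linear long-horizon dynamics,
covariate structure (age, sex, education), or correlated measurement error
across markers.  Passing tests therefore certify the estimator's behaviour
under its own assumptions, not clinical performance on real data.

## Numerical conventions and degenerate inputs

* Gradients are plain difference quotients $(x_2-x_1)/\Delta t$; `dt <= 0`
  is an error everywhere.
* An all-zero marker cannot be normalized and is refused by name.
* A rank-zero offset system (e.g. a cohort with no between-subject
  variation) yields $\mu = 0$, i.e. pure base-gradient extrapolation.
* With `recompute_base = TRUE`, LOO folds that lose a class are skipped with
  a warning; only if every fold is skipped does fitting fail.
* Stratified fold assignment deals shuffled subjects round-robin per class,
  so per-class fold sizes differ by at most one; a class smaller than the
  fold count is an error.
* All randomness (generator, fold shuffling) flows from explicit seeds, and
  the user's RNG state is restored afterwards; identical configurations
  produce byte-identical report files (`write_report()` prints doubles with
  17 significant digits).
* Model artifacts round-trip through versioned JSON at full double
  precision; shape or schema mismatches are explicit errors.

## Problem sizes used in the checks

The test suite exercises the estimator at sizes chosen to make each property
sharp while keeping the whole suite fast: exact weight recovery on a
noiseless coupled cohort of 50 subjects × 3 markers; noisy recovery at 200
subjects × 5 markers with 1 % noise; classification checks on cohorts of
55–120 subjects with 3–10 markers; the full nested loop at the default
49/70 design.  The acceptance script re-runs the pipeline at those same
sizes from scratch.

## Limitations

Forecasts are one-step-ahead only (the third visit from the first two);
recursing further compounds the linearity assumption and is out of scope.
No uncertainty intervals accompany forecasts.  The weight estimation is
unregularized beyond the minimum-norm pseudoinverse; ridge-type shrinkage
would be the natural next step for very wide marker panels.  Sensitivity and
specificity depend on the SVM's implicit threshold; no operating-point
tuning is performed.
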