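---
title: "Glymphatic MRI markers: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glymphatic MRI markers: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphr)
```

This vignette is the package's own account of the science it implements:
the two glymphatic-function markers, the statistical layer around them,
what the synthetic-data generators do and do not emulate, and the design
decisions taken where the methodology left genuine choices open.

## 1. The DTI-ALPS index

Water diffusion in the periventricular white matter is constrained by two
roughly orthogonal fibre systems: the superior corona radiata (SCR,
projection fibres running inferior–superior, z) and the superior
longitudinal fasciculus (SLF, association fibres running
anterior–posterior, y). The perivascular spaces of the medullary veins run
left–right (x), perpendicular to both. The ALPS idea is that diffusivity
along x, relative to diffusivity along the fibre axes, indexes how freely
fluid moves along the perivascular channel:

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx}^{proj},\, D_{xx}^{assoc})}
                       {\mathrm{mean}(D_{yy}^{proj},\, D_{zz}^{assoc})}$$

Each term is the mean of an axis-diffusivity map over a 5 mm spherical ROI.
The index is computed per hemisphere, and the mean index is the average of
the two hemispheric ratios — computed ratio-first, then averaged, which is
what the definition of the mean index as "the average of the left and
right indices" implies. ALPS is a dimensionless ratio; where cohort tables
attach a diffusivity unit label to it we treat that as a typographic
artifact and store it unitless.

**Tensor fit.** `fit_diffusion_tensor()` performs ordinary (unweighted)
log-linear least squares per voxel on $\ln S$ against the seven-column
design $[1, -b g_x^2, -b g_y^2, -b g_z^2, -2b g_xg_y, -2b g_xg_z,
-2b g_yg_z]$, matching the default behaviour of the standard FSL fitting
tool. Voxels containing any non-positive signal are excluded (the log is
undefined) and reported in a QC slot rather than clamped — clamping would
bias low-signal voxels. FA is computed from the tensor invariants
($\mathrm{FA}^2 = \tfrac32\,\|D - \tfrac{\mathrm{tr}}3 I\|_F^2 / \|D\|_F^2$,
identical to the eigenvalue formula and cheaper than a per-voxel
eigendecomposition), clamped to [0, 1] because noisy fits can imply
negative eigenvalues.

**ROI placement.** The four sphere centres are fixed 0-based voxel indices
on the 1 mm 182×218×182 FA template grid: left SCR (116, 110, 99), right
SCR (64, 110, 99), left SLF (128, 110, 99), right SLF (51, 110, 99). The
printed left/right pairs are not exactly mirror-symmetric; we take them as
printed rather than "correcting" them. On coarser grids the centres scale
by 1/voxel-size with round-half-even. Sphere membership is by
voxel-centre-to-centre distance ≤ radius, inclusive — a deterministic,
resolution-independent rule; on a 1 mm grid a 5 mm sphere contains 81
voxels, on a 2 mm grid 7 voxels. Registration to the template is out of
scope: inputs must already be template-space maps (or DWI acquired so that
the fit can run in template space).

## 2. gBOLD–CSF coupling

During global drops in cortical activity, CSF flows into the fourth
ventricle/foramen magnum region a few seconds later; the lagged
anti-correlation between the global gray-matter BOLD signal (gBOLD) and
the CSF inflow signal is therefore a functional marker of CSF dynamics.

`preprocess_signal()` drops the first 10 volumes, removes the linear
trend, applies a zero-phase forward–backward Butterworth band-pass
(0.01–0.1 Hz, order 4) and standardizes. Zero phase is essential because
the downstream statistic *is* a lag: a causal filter would shift the peak.
`cross_correlate()` evaluates Pearson correlations of gBOLD shifted by
$\tau$ against CSF over the truncated overlap window for
$\tau = -5 \dots +5$ TR, so negative $\tau$ means gBOLD leads. No zero
padding is used: with 11 lags on ~290 samples, truncation costs almost
nothing and avoids bias from artificial zeros.

The headline coupling strength is the *magnitude* of the correlation at
−3 TR, where the anti-correlation peaks at TR = 1.5 s; the signed value is
always reported alongside. Published cohort tables list positive coupling
values while the correlation at −3 TR is canonically negative; rather than
guess which convention a given table used, both numbers are emitted and
the magnitude is treated as the table-compatible quantity.

Two validations accompany the statistic. The negative-derivative check
cross-correlates $-\mathrm d(\mathrm{gBOLD})/\mathrm dt$ (central first
difference, one-sided ends) with CSF; its positive coupling peaks at 0 TR
when the inflow tracks the *decline* of the global signal. The permutation
null pairs the gBOLD series of subject $i$ with the CSF series of a
different subject $j \ne i$, cohort-wide, sampled with replacement over
10,000 draws; each subject's p-value is the add-one-corrected fraction of
null magnitudes at or above the observed one. Cohort-wide (rather than
within-group) pairing was chosen because the null hypothesis — no
subject-specific temporal coupling — does not involve group membership.

## 3. The statistical layer

Group comparisons follow the classical toolkit: one-way ANOVA, two-sample
t-tests, Pearson chi-square for sex, Kruskal–Wallis for clearly
non-normal scores, Bonferroni correction for pairwise post-hocs, partial
correlation (residualization on age, sex, education, disease duration and
H&Y stage) for marker–symptom relations, and plain Pearson correlation
between the two markers.

The t and F engines accept either raw vectors (delegated to
`stats::t.test` / `stats::oneway.test`) or `(n, mean, sd)` group
summaries, which are sufficient statistics for these tests; the two routes
agree to 10⁻¹⁰ when the summaries come from the same raw data, and this is
tested. Working from summaries lets published cohort tables be recomputed
exactly — the bundled tables reproduce their printed F, t and χ²
statistics within rounding of the printed summaries.

**Pooled vs Welch.** The choice between the pooled and Welch t is gated by
a two-sided F-ratio test of the two variances at α = 0.05, computed from
the summaries. Levene-type tests need raw data, so a summary-level gate is
the only reconstructible rule; this particular gate reproduces the
published mix (Welch-consistent for disease duration, pooled-consistent
for H&Y, UPDRS-III and LEDD). A Shapiro–Wilk wrapper is provided for raw
data, but when reproducing printed tables the variable-to-test assignment
follows the tables' own footnotes.

**Post-hoc convention.** The source methodology does not name its post-hoc
procedure; we use pooled-variance pairwise t-tests with Bonferroni
correction over the number of pairs, and report both raw and corrected
p-values.

## 4. Diagnostic models

`roc_auc()` computes AUC by the Mann–Whitney identity with ties counted
half, so it is invariant under monotone score transforms. For single
markers the direction is auto-chosen so AUC ≥ 0.5 (lower ALPS/coupling
indicates the anxious group) and recorded explicitly. Confidence intervals
use the DeLong placement-value variance with a normal approximation,
clipped to [0, 1]; `delong_test()` compares two correlated AUCs through
the placement-value covariance. The operating point maximizes Youden's J,
with ties resolved toward higher specificity; published
sensitivity/specificity pairs do not always name their criterion (one
reported specificity-1 operating point suggests a different rule), so the
operating point is derived from the returned curve and the convention is
explicit rather than hidden.

The multivariate model is maximum-likelihood logistic regression on
standardized predictors — the standard two-class clinical combiner; the
source does not name its model, and the choice is declared in the output
metadata. On (quasi-)separation the fit falls back to a lightly
ridge-penalized IRLS with a warning, keeping the score finite. Because AUC
is rank-based, a single-predictor "combined" model reproduces that
marker's ROC exactly.

## 5. The synthetic-data module

The generators define the study conditions for every test in the package.
They are first-class, tested code, not ad-hoc fixtures.

**DWI phantoms.** Piecewise-constant diagonal-tensor regions (boxes around
the four ROI centres) in an isotropic background, sampled with one b = 0
volume and 64 Fibonacci-sphere directions at b = 1000 s/mm², following
S = S0·exp(−b gᵀDg) exactly before noise. Defaults: 91×109×91 grid at
2 mm; projection tensor diag(1.00, 0.68, 1.45)×10⁻³ mm²/s, association
tensor diag(0.82, 1.35, 0.68)×10⁻³, background 0.7×10⁻³ — physiologically
plausible values chosen once to give a ground-truth ALPS of 1.338,
matching the healthy range in the motivating cohort. Noise is additive
Gaussian by default (SNR = S0/σ; σ = 0.05 gives SNR 20), with an optional
Rician magnitude model (Gaussian on two quadrature channels); Gaussian is
the default because it is the simpler adequate model for recovery tests.
The one C++ kernel in the package synthesizes the signal volume; it draws
noise through R's `norm_rand()`, so a seed fully determines the output.

**Coupled series.** A delay-and-scale model: gBOLD is smoothed white noise
(Gaussian FWHM 6 s), CSF is the 3-sample-delayed copy scaled so that
`amplitude` *is* the population correlation magnitude
(csf = sign·(A·lagged + √(1−A²)·white)), plus optional extra white noise;
the expected correlation at the coupling lag is then
sign·A/√(1+σ²), which the attenuation tests use as their analytic target.
Defaults (300 points, TR 1.5 s, lag 3, sign −1, amplitude 0.35) mirror the
acquisition and the observed coupling magnitudes. No hemodynamic model is
claimed — the construction reproduces exactly the lagged anti-correlation
structure the coupling statistic measures, nothing more.

**Cohorts.** Per group, variables are normal draws with the bundled
summary-table means/SDs (sex: Bernoulli with the printed M/F proportion);
between-subject SDs are used as total variance because within-subject
variance is not characterized in the source. Within each group the markers
load on the subject's standardized HAMA score through a shared Gaussian
factor. The loading is *calibrated*: the group-mean differences printed in
the tables already induce a pooled marker–HAMA correlation (about −0.21
for ALPS before any within-group coupling), so the generator solves, in
closed form from the two-group mixture moments, for the within-group
loading that makes the *population partial correlation given the five
covariates* equal the requested target (defaults −0.244/−0.280 for
left/right ALPS, −0.317 for coupling). An unattainable target (implied
loading ≥ 1) raises an "infeasible correlation target" error. Left and
right ALPS share a subject-level trait (default within-group correlation
0.8, the value implied by the printed SD of the mean index), and
`alps_mean` is always derived as the average. Group labels can optionally
be reassigned by the HAMA ≥ 14 rule after simulation.

What the generators deliberately do **not** emulate: scanner artifacts
(motion, eddy currents, Gibbs ringing, susceptibility distortion — those
belong to preprocessing stages the package consumes, not reimplements),
spatially varying tensors, hemodynamic response shapes, non-normal
clinical score distributions, and missingness. Passing tests therefore
demonstrate correctness of the estimators under the stated models, not
robustness to real-world artifacts.

## 6. Numerical choices and problem sizes

* Band-pass: Butterworth order 4, applied forward–backward
  (`signal::filtfilt`); measured gain ≥ 0.999 at 0.05 Hz and ≤ 0.001 at
  0.2 Hz on 290-sample series.
* A series that is constant after detrending/filtering (e.g. a pure ramp)
  is returned as zeros with a warning instead of dividing by a ~0 SD.
* Cross-correlation at a lag with a zero-variance overlap window yields NA
  with a warning; the coupling strength errors if its quantification lag
  is undefined.
* Sphere membership uses squared distances with a 10⁻⁹ tolerance so that
  boundary voxels at exactly the radius are included deterministically.
* Tensor fits guard against under-determination twice: at least six
  distinct directions up to sign, and design rank 7.
* The p-value of the permutation null uses the add-one correction, so
  p ∈ (0, 1] and is never exactly zero.
* Test problem sizes are chosen to exercise the stated study conditions
  while keeping the default suite fast: the phantom-recovery study runs
  100 phantoms at the full reduced grid (91×109×91, 65 volumes), the
  permutation calibration 500 subjects × 10,000 pairings, the DeLong
  bootstrap oracle 20,000 replicates, and the cohort-ordering study
  60–200 simulated cohorts.
* Monte-Carlo calibration checks are written as sound joint tests: a set
  of ~N(0,1) standardized deviations is required to be ~90% within 2 SE
  with a hard cap at 4.5 SE, rather than demanding every draw fall within
  2 SE (which a correct generator would fail with ~30 simultaneous
  checks); correlation-recovery checks compare the *mean* estimate over
  10 generator replicates against a ±0.03 band.

## 7. Known limitations

* ALPS is computed on template-space maps; registration quality is the
  caller's responsibility, and no free-water or along-tract correction is
  attempted.
* The permutation null assumes equal series length across subjects and
  exchangeability of CSF series between subjects under the null.
* The DeLong normal approximation is known to be anti-conservative for
  very small or highly separated samples; the bootstrap comparison in the
  test suite covers the 20-subject regime used here.
* Summary-statistic tests can only reproduce what (n, mean, SD) determine:
  rank-based statistics (Kruskal–Wallis) need raw data, and printed H
  values from rounded summaries are not recomputable.
* The cohort simulator's partial-correlation calibration is exact for the
  population; finite cohorts at the published sizes still show sampling
  scatter of about ±0.12 in a single draw.
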