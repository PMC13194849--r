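---
title: "Bone-marrow FDG kinetics and prognostic modelling: methods"
author: "bmkinetics developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone-marrow FDG kinetics and prognostic modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmkinetics)
```

## The problem

Among advanced NSCLC patients who reach a partial response on first-line
therapy, progression risk is heterogeneous and poorly predicted by static
PET metrics (SUVmax, MTV, TLG) or routine clinical covariates. Dynamic
FDG-PET offers a richer signal: the time-activity curve (TAC) of a region
of interest can be decomposed, through the two-tissue compartment (2TC)
model, into a vascular component $C_b$, a free (interstitial/extracellular)
component $C_f$, and a metabolized (phosphorylated, trapped) component
$C_m$. The washout slope of the *bone-marrow* free component between 10 and
30 minutes — here called BCS (`BM_Cf_Slope_10_30`) — is the candidate
biomarker: a steeper (more negative) decline of free tracer in the marrow
interstitium is read as a dysfunctional, high-risk marrow niche.

This package implements the full analysis chain — kinetic decomposition,
TAC feature engineering, bootstrap-LASSO-Cox stable feature selection,
single-feature risk stratification and time-dependent evaluation — plus a
synthetic cohort generator with known ground truth, because no public
patient-level dataset exists for this design.

## The kinetic model

The 2TC state equations with rate constants $K_1$ (blood to tissue,
mL/min/mL), $k_2$ (efflux), $k_3$ (phosphorylation), $k_4$
(dephosphorylation, all 1/min) are

$$\frac{dC_f}{dt} = K_1 C_b - (k_2 + k_3) C_f + k_4 C_m, \qquad
  \frac{dC_m}{dt} = k_3 C_f - k_4 C_m,$$

with zero initial conditions, and the measured tissue concentration is

$$C_T(t) = (1 - v_b)\,(C_f(t) + C_m(t)) + v_b\, C_b(t),$$

where $v_b$ is the fractional blood volume. `model_curves()` evaluates the
analytic impulse response (a two-exponential with rates given by the
eigenvalues of the system) convolved with the input function. The input is
treated as piecewise linear between its samples, and the per-interval
convolution integrals are computed in closed form (an exponential
integrator), so the solution is exact for the interpolated input up to
machine precision. The tests verify this against two independent oracles: a
fourth-order Runge-Kutta integration of the state equations and a direct
Richardson-extrapolated trapezoid convolution.

### Fitting

`fit_2tc()` matches the *frame-averaged* model curve to the measured
per-frame values — not a midpoint evaluation — because the early 10-s
frames straddle the steep bolus transit. It minimizes a weighted residual
sum of squares with weights proportional to frame duration (a count-rate
surrogate; the acquisition protocol gives no scan-specific weights), under
box bounds $K_1, k_2 \in [0,2]$, $k_3 \in [0,1]$, $k_4 \in [0, 0.05]$,
$v_b \in [0, 0.3]$. These are generous physiologic FDG ranges; the tight
$k_4$ cap keeps the exchange rates identifiable on nearly flat marrow
curves. $k_4$ is estimated by default and can be fixed at 0
(`fit_options(fix_k4 = TRUE)`) for the irreversible model.

The objective is multi-modal at PET noise levels, so the optimizer
(L-BFGS-B) is multi-started: 8 fixed coarse-grid starts plus 4 seeded
jittered starts by default, ties broken by lower WRSS then lower $k_4$, and
the winner is polished at tight tolerance. Non-convergence across all
starts is flagged on the result, and `decompose()` refuses non-converged
fits rather than silently propagating them.

### Frame schedule and time origin

The default schedule is 28 frames over 65 min (6×10 s, 4×30 s, 4×60 s,
4×120 s, 10×300 s). The package places $t = 0$ at tracer arrival at the
start of the dynamic acquisition, so the 10-, 30- and 60-min feature
anchors fall inside the scan. The alternative reading — an hour-long
uptake period *before* the dynamic scan — is irreconcilable with 10-s
bolus-capture frames and with features named "10–30 min post-injection";
this choice is deliberate and documented rather than inherited.

## TAC features

Six operators are applied to the decomposed component curves, sampled at
frame mid-times with linear interpolation at the 10/30/60-min anchors:

* `Slope_10_30`: $(TAC(30) - TAC(10)) / 20$ — rise-over-run, so a
  declining curve yields a **negative** value. The uniform
  (later − earlier)/Δt convention is used for every slope, including
  `Slope_max_60`. (A printed-formula variant with the numerator reversed
  would flip the sign of the biomarker and contradict its negative
  reported cutoff; this package uses the self-consistent convention
  throughout.)
* `AUC_T`: trapezoidal area under the whole curve.
* `Slope_0_max`, `Slope_max_60`, `Time_TM`, `TAC_max`: peak value, earliest
  peak time (ties go to the earliest sample), pre-peak and post-peak
  slopes, with the degenerate cases (peak at the first sample; peak at or
  after 60 min) defined as 0.

Each ROI contributes 14 features — all six on $C_f$ and $C_b$, and
`Slope_0_max` + `TAC_max` only on the monotonically growing $C_m$ — for a
28-feature kinetic vector over tumor and bone marrow, with a frozen naming
contract (`kinetic_feature_names()`; `BM_Cf_Slope_10_30` is BCS).
Conventional metrics (SUVmax/mean/min per ROI, MTV as the volume of voxels
with SUV ≥ 2.5, TLG = MTV × mean supra-threshold SUV) come from voxel SUV
arrays.

## Feature selection and modelling

`bootstrap_selection()` draws B = 1000 patient-level bootstrap resamples
(configurable); each resample runs LASSO-Cox with 5-fold event-stratified
cross-validation and the 1-SE rule on a 100-point log-spaced λ grid
spanning four decades below the all-zero λ. Features are z-scored inside
every fit, so selection is invariant to affine rescaling and column order.
Features selected in strictly more than 50% of resamples form the stable
set. Resamples that cannot support a penalized fit (e.g. too few events)
select nothing and are counted.

The stable set enters a multivariate Cox model (Efron ties, Wald CIs,
likelihood-ratio test). Discrimination is summarized by Harrell's C-index
with Harrell's bootstrap optimism correction: refit on each resample,
subtract the mean of (resample C − original-data C of the refit model).
Proportional hazards are checked with score tests on scaled Schoenfeld
residuals (KM time transform), per covariate and globally.

## Stratification and evaluation

* `optimal_logrank_cutoff()` scans midpoints between consecutive distinct
  marker values, requiring each induced group to hold ≥ 15% of patients
  and ≥ 3 patients (an unconstrained scan at n ≈ 32 produces degenerate
  splits), and maximizes the log-rank statistic. The reported p-value is
  the naive one; the maximally selected search inflates type-I error, and
  a property test documents that inflation rather than hiding it.
* `td_auc()` implements the cumulative-case/dynamic-control ROC with plain
  Kaplan-Meier weighting (no nearest-neighbour smoothing). On uncensored
  data it reduces exactly to the Mann-Whitney rank statistic; this is a
  frozen test.
* `calibration_at()` reports the IPCW Brier score at the horizon, a binned
  KM-observed vs mean-predicted curve, and a recalibration slope/intercept
  on the complementary-log-log scale (slope = Cox coefficient of
  $\log(-\log(1-\hat r))$, ideal 1; intercept = observed minus predicted
  cloglog risk, ideal 0). With a refit function the slope/intercept are
  optimism-corrected by the same bootstrap scheme as the C-index; constant
  predictions make the slope undefined and are flagged, not guessed.
* `decision_curve()` computes survival-data net benefit
  $NB(p_t) = TP/n - FP/n \cdot p_t/(1-p_t)$ with KM-estimated event
  probabilities among test-positives, against treat-all and treat-none.
* Horizons given in months use 1 month = 30.4375 days.
* `compare_groups()` reproduces the baseline-table statistics: Shapiro-Wilk
  gate at α = 0.05, then Welch t-test or Mann-Whitney U; Fisher's exact
  test for categoricals (seeded Monte-Carlo with ≥ 10^5 draws beyond 2×2).

The 12-month predicted risks used for calibration and decision curves come
from a univariable Cox model on the selected marker with a Breslow
baseline — the simplest defensible construction for a single-feature tool.

## The synthetic cohort: what it emulates, and what it does not

`gen_cohort()` produces a complete stated world:

* **Input function**: a Feng-style tri-exponential bolus,
  $C_b(t) = (A_1 s - A_2 - A_3)e^{-\lambda_1 s} + A_2 e^{-\lambda_2 s} +
  A_3 e^{-\lambda_3 s}$, $s = t - t_0$, with defaults (A1 = 300 kBq/mL/min,
  λ1 = 4/min, A2 = 3, λ2 = 0.5, A3 = 2.5, λ3 = 0.01/min, t0 = 0.1 min)
  giving a ~28 kBq/mL peak shortly after arrival and a slowly decaying
  ~1.5 kBq/mL tail — typical magnitudes for a 3.5 MBq/kg injection. An
  image-derived aortic input cannot be reproduced without images, so the
  parametric form stands in for it.
* **Kinetics**: per-patient uniform draws within physiologic ranges — an
  avid tumor (K1 0.08–0.25, k2 0.2–0.6, k3 0.04–0.12, k4 ≤ 0.008,
  v_b 0.03–0.15) and low-uptake vertebral marrow (K1 0.04–0.12,
  k2 0.15–0.5, k3 0.01–0.05, k4 ≤ 0.005, v_b 0.02–0.10).
* **Noise**: zero-mean Gaussian per frame with variance proportional to
  value/frame-duration (the standard dynamic-PET weighting heuristic),
  scaled so `noise_level` is roughly the relative error of a typical
  frame: $\sigma_i = \eta \sqrt{C_i\, \bar C\, \bar\Delta / \Delta_i}$
  with $\bar C$ the mean positive frame value and $\bar\Delta$ the mean
  frame duration. Default η = 0.05.
* **Outcome coupling**: progression-free survival is exponential with
  hazard $h_0 \exp(\beta z)$, where $z$ is the within-cohort standardized
  *true* bone-marrow $C_f$ slope over 10–30 min and β = −2.3 per SD by
  default (the scale of the reported multivariate coefficient). Censoring
  is the minimum of an administrative time (900 days) and an independent
  uniform draw on (0, 2 × 900) days — a simple loss-to-follow-up model the
  source protocol does not specify. `calibrate_baseline_hazard()` solves
  for $h_0$ against the priors' implied slope distribution; the default
  $h_0 = 0.00187$/day is that calibration's output for an expected 17/32
  event fraction, matching the reference cohort shape (n = 32, 17
  progressors).
* **Conventional-feature support**: voxel SUV phantoms with closed-form
  MTV/TLG truths (voxel volume 0.0207 mL, the scanner's reconstruction
  voxel).

What it deliberately does **not** emulate: 4D image formation, scanner
physics (PSF, attenuation, scatter), motion, partial-volume effects,
segmentation error, inter-patient input-function variability, correlated
clinical confounding, or non-proportional hazards. A green end-to-end test
therefore establishes that the *pipeline* recovers a planted
marker-outcome coupling through the full fit-decompose-select-evaluate
chain at realistic n and noise — not that the biomarker is valid in
patients.

One emergent property worth knowing: under these priors the bone-marrow
`Cf` slope and `Cf` AUC are strongly collinear (|r| ≈ 0.95+), so at n = 32
stability selection sometimes crowns the AUC surrogate instead of the
slope in an individual replicate — the same behaviour as correlated
features in any LASSO at small n, and the reason the end-to-end acceptance
criterion is majority-of-replicates rather than per-replicate.

## Numerical and design choices

* Eigen-decomposition degeneracy (repeated exponents, possible when
  $k_3 \approx 0$ and $k_2 \approx k_4$) is handled by a 1e-7 nudge of
  $k_3$.
* `frame_average()` integrates the piecewise-linear curve exactly by
  including the curve's own sample points in the sub-grid.
* All randomness flows from one seed through fixed named substreams
  (`derive_seed`), so every artifact is bit-reproducible; the pipeline
  writes a manifest with the seed and a config fingerprint.
* Bootstrap resamples are plain (not event-stratified): the reference
  procedure does not state stratification, and plain resampling is the
  default in the field; resamples with too few events are dropped and
  counted instead.
* Multi-level clinical covariates are one-hot encoded against the first
  level for the selection pool.
* Runtime scalings used by the acceptance tests (smaller bootstrap B,
  50-point λ grids, reduced multi-start) are labelled inline in
  `tests/testthat/test-acceptance.R`; statistical targets and tolerances
  are never scaled.

## Known limitations

* The Heagerty-style KM estimator of time-dependent sensitivity/specificity
  can be non-monotone under heavy censoring; points are sorted before
  trapezoidal integration, as in the reference implementations.
* The calibration intercept is a population-level cloglog contrast, not a
  Poisson-offset regression; with a refit function it is optimism-corrected,
  otherwise only percentile CIs are reported.
* The optimal-cutoff p-value is intentionally naive (see above).
* The 2TC fit assumes a noiseless, given input function; input-function
  error propagates directly into $K_1$-scaled quantities.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cohort <- gen_cohort(cohort_spec(seed = 1))          # n = 32, ~17 events
report <- run_pipeline(pipeline_config(
  cohort = cohort_spec(seed = 1),
  selection = selection_config(B = 200, seed = 1),
  seed = 1))
print(report)
```

See the README for the printed output of this example and its reading.
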