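# bmkinetics

Prognostic modelling of dynamic FDG-PET bone-marrow kinetics for advanced
NSCLC partial responders — as a tested, reusable R pipeline exercised on
fully synthetic cohorts.

## The problem and who this is for

Patients with advanced non-small-cell lung cancer who achieve a partial
response to first-line therapy still progress at very different rates, and
neither static PET metrics (SUVmax, MTV, TLG) nor routine clinical
covariates separate them well. Dynamic PET can: the measured tissue
time-activity curve (TAC) of a region decomposes, under the two-tissue
compartment model

    C_T(t) = (1 - v_b) (C_f(t) + C_m(t)) + v_b C_b(t)

    dC_f/dt = K1 C_b - (k2 + k3) C_f + k4 C_m
    dC_m/dt = k3 C_f - k4 C_m

into vascular (C_b), free (C_f) and metabolized (C_m) components. The
washout slope of the **bone-marrow free component between 10 and 30 min**
(`BM_Cf_Slope_10_30`, "BCS", kBq/mL/min; negative = declining) is the
candidate biomarker: steeper free-tracer clearance in the marrow
interstitium flags a high-risk host state.

The package is for methodologists and imaging scientists who want the
whole chain — 2TC fitting and decomposition, TAC feature engineering,
bootstrap-LASSO-Cox stable selection, optimism-corrected concordance,
log-rank optimal-cutoff stratification, time-dependent ROC / calibration /
decision-curve evaluation — with every stage testable against planted
ground truth, because the motivating patient dataset is private.

## What it provides

| stage | functions |
|---|---|
| synthetic cohorts with known truth | `cohort_spec()`, `gen_cohort()`, `simulate_patient()`, `gen_input_function()`, `calibrate_baseline_hazard()`, `gen_voxel_phantom()` |
| kinetics | `model_curves()`, `frame_average()`, `fit_2tc()`, `decompose()` |
| features | `slope_between()`, `auc_t()`, `peak_features()`, `extract_feature_vector()` (28 kinetic features, frozen names), `conventional_features()` |
| selection & modelling | `lasso_cox_cv()`, `bootstrap_selection()`, `fit_cox()`, `optimism_corrected_cindex()`, `ph_test()` |
| stratification & evaluation | `optimal_logrank_cutoff()`, `km_estimate()`, `logrank_test()`, `td_auc()`, `calibration_at()`, `decision_curve()`, `compare_groups()` |
| orchestration & I/O | `run_pipeline()`, `pipeline_config()`, `bmk_main()` (CLI), TAC/cohort/feature CSV dialects, JSON reports |

## Worked example

A paper-shaped synthetic cohort (n = 32, ~17 progression events, hazard
coupled at log-HR −2.3 per SD of the true bone-marrow C_f slope), run end
to end:

```r
library(bmkinetics)
report <- run_pipeline(pipeline_config(
  cohort    = cohort_spec(seed = 1),
  selection = selection_config(B = 100, seed = 1),
  fit       = fit_options(n_grid_starts = 4, n_jitter_starts = 2),
  B_eval = 100, B_cindex = 100, seed = 1))
print(report)
#> <bmk_report>
#>   top feature: BM_Cf_AUC_T (stable set: BM_Cf_AUC_T)
#>   C-index: apparent 0.842, optimism-corrected 0.848
#>   cutoff 37.387 (log-rank chi2 25.51, naive p 4.4e-07)
#>   AUC @ 12 months: 0.861
#>   AUC @ 18 months: 0.888
#>   AUC @ 24 months: 0.896
#>   Brier 0.131, calibration slope 1.075, intercept -0.067
```

Reading this: bootstrap-LASSO-Cox found one stable feature (selection
frequency > 50% across 100 resamples). In this replicate it is the
bone-marrow free-component AUC rather than the planted slope — the two are
nearly collinear (|r| ≈ 0.95+) under the generator's priors, so either can
head the stable set at n = 32; across replicates the slope wins the
majority (that is an acceptance criterion). The optimism-corrected C-index
(~0.85) shows the marrow kinetic signal survives internal validation; the
log-rank optimal cutoff splits the cohort into clearly separated risk
groups; time-dependent AUCs at 12/18/24 months and a near-ideal
calibration slope (~1) quantify discrimination and calibration of the
single-feature tool, and `report$dca` holds the net-benefit table.

Command-line equivalent:

```sh
Rscript inst/scripts/bmkinetics.R run-all --seed 1 --B 100 --out out/
Rscript inst/scripts/bmkinetics.R simulate --seed 7 --n 32 --out sim/
```

## Layout notes

The methods vignette (`vignettes/bmkinetics-methods.Rmd`) documents the
model, the generator's stated world and its limits, and every numerical
design choice; the CSV/JSON dialects are described on the I/O functions'
help pages.
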