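## End-to-end orchestration: simulate -> fit -> features -> select ->
## stratify -> evaluate, with CSV/JSON artifacts and a reproducibility
## manifest. Every stochastic stage draws from a named substream of the
## single global seed.

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()] (used when simulation is enabled).
#' @param selection a [selection_config()].
#' @param fit a [fit_options()] list for the per-patient 2TC fits.
#' @param horizons_months evaluation horizons in months (positive,
#'   increasing; default 12, 18, 24).
#' @param B_eval bootstrap repetitions for evaluation CIs / calibration.
#' @param B_cindex bootstrap repetitions for the optimism-corrected C-index.
#' @param min_group_frac admissibility constraint for the optimal cutoff.
#' @param dca_thresholds decision-curve threshold grid.
#' @param seed global seed; overrides the cohort spec seed.
#' @param out_dir optional output directory for artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            selection = selection_config(B = 200),
                            fit = fit_options(),
                            horizons_months = c(12, 18, 24),
                            B_eval = 200, B_cindex = 200,
                            min_group_frac = 0.15,
                            dca_thresholds = seq(0.05, 0.95, by = 0.05),
                            seed = 1L, out_dir = NULL) {
  assert_that(all(horizons_months > 0) && !is.unsorted(horizons_months, strictly = TRUE),
              "horizons must be positive and increasing")
  cohort$seed <- as.integer(seed)
  selection$seed <- derive_seed(seed, 2)
  fit$seed <- derive_seed(seed, 3)
  structure(list(cohort = cohort, selection = selection, fit = fit,
                 horizons_months = horizons_months, B_eval = B_eval,
                 B_cindex = B_cindex, min_group_frac = min_group_frac,
                 dca_thresholds = dca_thresholds, seed = as.integer(seed),
                 out_dir = out_dir), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Per-patient kinetic fits and feature extraction for a cohort
#'
#' Fits the 2TC model to the tumor and bone-marrow frame TACs of every
#' patient (shared blood input), decomposes them, and assembles the
#' 28-feature kinetic vector plus the 8 conventional metrics.
#'
#' @param cohort a `bmk_cohort` (or a compatible list with `tac`, `input`,
#'   `survival`, `phantoms`, `spec`).
#' @param fit_opts a [fit_options()] list.
#' @return data.frame: `patient_id`, 28 kinetic features, 8 conventional
#'   features; attribute `fits` holds the per-patient fit objects.
#' @export
cohort_features <- function(cohort, fit_opts = fit_options()) {
  sched <- cohort$spec$schedule
  ids <- sort(unique(cohort$survival$patient_id))
  fits <- list()
  rows <- lapply(ids, function(id) {
    dec <- lapply(c(tumor = "tumor", bone_marrow = "bone_marrow"), function(roi) {
      sub <- cohort$tac[cohort$tac$patient_id == id & cohort$tac$roi == roi, ]
      sub <- sub[order(sub$frame_start_s), ]
      f <- fit_2tc(sub$activity_kbq_per_ml, cohort$input, sched, fit_opts)
      if (!f$converged)   # retry once with the full multi-start defaults
        f <- fit_2tc(sub$activity_kbq_per_ml, cohort$input, sched,
                     fit_options(seed = fit_opts$seed))
      fits[[paste(id, roi)]] <<- f
      decompose(f)
    })
    kin <- extract_feature_vector(dec$tumor, dec$bone_marrow)
    ph <- cohort$phantoms[[match(id, ids)]]
    conv <- conventional_features(ph$tumor$suv, ph$bone_marrow$suv,
                                  ph$tumor$voxel_volume_mL)
    c(patient_id = id, kin, conv)
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "fits") <- fits
  out
}

#' Candidate matrix for feature selection
#'
#' Binds clinical covariates (one-hot encoding any non-numeric column),
#' conventional metrics and kinetic features into one numeric matrix.
#'
#' @param features feature data.frame (from [cohort_features()] or
#'   [read_feature_csv()]).
#' @param clinical optional data.frame of clinical covariates, rows aligned
#'   with `features`.
#' @return numeric matrix with named columns.
#' @export
candidate_matrix <- function(features, clinical = NULL) {
  x <- as.matrix(features[, setdiff(names(features), "patient_id"),
                          drop = FALSE])
  if (!is.null(clinical) && ncol(clinical)) {
    enc <- lapply(names(clinical), function(nm) {
      v <- clinical[[nm]]
      if (is.numeric(v)) {
        m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      } else {
        f <- as.factor(v)
        m <- sapply(levels(f)[-1], function(lv) as.numeric(f == lv))
        if (is.null(dim(m))) m <- matrix(m, ncol = nlevels(f) - 1)
        colnames(m) <- paste(nm, levels(f)[-1], sep = "_")
        m
      }
      m
    })
    x <- cbind(do.call(cbind, enc), x)
  }
  storage.mode(x) <- "double"
  x
}

## 12-month-style predicted event risks from a univariable Cox model with
## Breslow baseline
cox_risk_at <- function(marker, time, status, horizon) {
  df <- data.frame(m = marker, time = time, status = status)
  ## monotone likelihood on very small cohorts only inflates the coefficient;
  ## the derived risks stay ordered, so keep the console quiet
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, status) ~ m, data = df))
  bh <- survival::basehaz(fit, centered = TRUE)
  H0 <- if (any(bh$time <= horizon)) max(bh$hazard[bh$time <= horizon]) else 0
  lp <- predict(fit, type = "lp")
  risk <- 1 - exp(-H0 * exp(lp))
  list(risk = pmin(pmax(risk, 1e-6), 1 - 1e-6), lp = lp, fit = fit, H0 = H0)
}

#' Run the full pipeline on a synthetic (or supplied) cohort
#'
#' simulate -> fit -> features -> select -> stratify -> evaluate. When
#' `config$out_dir` is set, every artifact is written there along with a
#' manifest (seed, config fingerprint, package version).
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built `bmk_cohort`; by default one is
#'   generated from `config$cohort`.
#' @return list of class `bmk_report`: `selection`, `cox` (coefficient
#'   table), `cindex`, `ph`, `stratification` (cutoff, log-rank), `auc`
#'   (per horizon), `calibration`, `dca`, `top_feature`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  cohort <- stage("simulate", cohort %||% gen_cohort(config$cohort))
  surv <- cohort$survival

  feats <- stage("features", cohort_features(cohort, config$fit))
  clinical <- surv[, setdiff(names(surv), c("patient_id", "pfs_days", "event")),
                   drop = FALSE]
  x <- stage("features", candidate_matrix(feats, clinical))

  selres <- stage("select",
                  bootstrap_selection(x, surv$pfs_days, surv$event,
                                      config$selection))
  stable <- selres$stable
  if (!length(stable)) stable <- selres$freq$feature[1]  # fallback: top frequency

  cox <- stage("select",
               fit_cox(x[, stable, drop = FALSE], surv$pfs_days, surv$event))
  cidx <- stage("select",
                optimism_corrected_cindex(x[, stable, drop = FALSE],
                                          surv$pfs_days, surv$event,
                                          B = config$B_cindex,
                                          seed = derive_seed(config$seed, 11)))
  ph <- stage("select", ph_test(cox))

  top <- stable[1]                      # ordered by frequency
  marker <- x[, top]
  strat <- stage("stratify",
                 optimal_logrank_cutoff(marker, surv$pfs_days, surv$event,
                                        config$min_group_frac))

  horizons <- months_to_days(config$horizons_months)
  cr <- stage("evaluate", cox_risk_at(marker, surv$pfs_days, surv$event,
                                      horizons[1]))
  aucs <- stage("evaluate", lapply(seq_along(horizons), function(i) {
    a <- td_auc(cr$lp, surv$pfs_days, surv$event, horizons[i],
                B_ci = config$B_eval, seed = derive_seed(config$seed, 21 + i))
    list(months = config$horizons_months[i], auc = a$auc, ci = a$ci)
  }))
  refit <- function(idx) {
    rb <- cox_risk_at(marker[idx], surv$pfs_days[idx], surv$event[idx],
                      horizons[1])
    lp_orig <- unname(coef(rb$fit)[1]) * (marker - mean(marker[idx]))
    list(boot = rb$risk,
         orig = pmin(pmax(1 - exp(-rb$H0 * exp(lp_orig)), 1e-6), 1 - 1e-6))
  }
  cal <- stage("evaluate",
               calibration_at(cr$risk, surv$pfs_days, surv$event, horizons[1],
                              B = config$B_eval, seed = derive_seed(config$seed, 31),
                              refit_fun = refit))
  dca <- stage("evaluate",
               decision_curve(cr$risk, surv$pfs_days, surv$event, horizons[1],
                              config$dca_thresholds))

  manifest <- list(seed = config$seed,
                   n_patients = nrow(surv), n_events = sum(surv$event),
                   horizons_months = config$horizons_months,
                   selection_B = config$selection$B,
                   config_fingerprint = config_fingerprint(config),
                   package_version = as.character(utils::packageVersion("bmkinetics")))

  report <- structure(list(
    selection = selres$freq, stable = selres$stable, top_feature = top,
    cox = cox$table, lr = list(stat = cox$lr_stat, p = cox$lr_p),
    cindex = cidx, ph = ph,
    stratification = list(cutoff = strat$cutoff, statistic = strat$statistic,
                          p = strat$p, high_risk = strat$high_risk),
    auc = aucs,
    calibration = list(brier = cal$brier, intercept = cal$intercept,
                       slope = cal$slope, corrected = cal$corrected),
    dca = dca, manifest = manifest), class = "bmk_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_tac_csv(cohort$tac, file.path(od, "tac.csv"))
    write_cohort_csv(surv, file.path(od, "cohort.csv"))
    write_feature_csv(feats, file.path(od, "features.csv"))
    write.csv(selres$freq, file.path(od, "selection.csv"), row.names = FALSE)
    write.csv(dca, file.path(od, "dca.csv"), row.names = FALSE)
    km <- km_estimate(surv$pfs_days, surv$event)
    write.csv(km, file.path(od, "km.csv"), row.names = FALSE)
    truth <- list(slopes = cohort$slopes, z = cohort$z,
                  effect_size = cohort$spec$effect_size,
                  baseline_hazard = cohort$spec$baseline_hazard)
    write_report_json(truth, file.path(od, "truth.json"))
    write_report_json(report_to_list(report), file.path(od, "report.json"))
    write_report_json(manifest, file.path(od, "manifest.json"))
  }
  report
}

## deterministic fingerprint of the scalar configuration fields
config_fingerprint <- function(config) {
  s <- jsonlite::toJSON(list(seed = config$seed,
                             n = config$cohort$n_patients,
                             effect = config$cohort$effect_size,
                             h0 = config$cohort$baseline_hazard,
                             noise = config$cohort$noise_level,
                             B = config$selection$B,
                             horizons = config$horizons_months),
                        auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 4294967291)
}

report_to_list <- function(r) {
  list(top_feature = r$top_feature, stable = as.list(r$stable),
       selection = r$selection, cox = r$cox, lr = r$lr,
       cindex = r$cindex[c("apparent", "corrected", "ci")],
       stratification = r$stratification,
       auc = r$auc,
       calibration = r$calibration, dca = r$dca, manifest = r$manifest)
}

#' @export
print.bmk_report <- function(x, ...) {
  cat("<bmk_report>\n")
  cat(sprintf("  top feature: %s (stable set: %s)\n", x$top_feature,
              paste(x$stable, collapse = ", ")))
  cat(sprintf("  C-index: apparent %.3f, optimism-corrected %.3f\n",
              x$cindex$apparent, x$cindex$corrected))
  cat(sprintf("  cutoff %.5g (log-rank chi2 %.2f, naive p %.3g)\n",
              x$stratification$cutoff, x$stratification$statistic,
              x$stratification$p))
  for (a in x$auc)
    cat(sprintf("  AUC @ %d months: %.3f\n", a$months, a$auc))
  cat(sprintf("  Brier %.3f, calibration slope %.3f, intercept %.3f\n",
              x$calibration$brier, x$calibration$slope, x$calibration$intercept))
  invisible(x)
}
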