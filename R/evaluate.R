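## Model evaluation for the simplified single-feature tool: time-dependent
## ROC (cumulative-case / dynamic-control, Kaplan-Meier form), calibration at
## a fixed horizon (IPCW Brier, binned curve, recalibration slope/intercept)
## and decision-curve analysis for survival data.

DAYS_PER_MONTH <- 30.4375

#' Convert horizons in months to days
#' @param months numeric vector of months.
#' @return days (1 month = 30.4375 days).
#' @export
months_to_days <- function(months) months * DAYS_PER_MONTH

## ROC points of the cumulative/dynamic KM estimator; marker oriented so
## larger values mean higher risk
td_roc_points <- function(marker, time, status, horizon) {
  s_all <- km_surv_at(time, status, horizon)
  if (s_all >= 1) stop_input("no cases by the horizon")
  if (s_all <= 0) stop_input("no controls by the horizon")
  cuts <- sort(unique(marker))
  tpr <- numeric(length(cuts)); fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pos <- marker > cuts[i]
    p_pos <- mean(pos)
    s_pos <- if (any(pos)) km_surv_at(time[pos], status[pos], horizon) else 1
    s_neg <- if (any(!pos)) km_surv_at(time[!pos], status[!pos], horizon) else 1
    tpr[i] <- (1 - s_pos) * p_pos / (1 - s_all)
    fpr[i] <- 1 - s_neg * (1 - p_pos) / s_all
  }
  ## zap floating noise so exactly-tied FPR values group before the
  ## secondary TPR sort (keeps the uncensored case exactly the rank statistic)
  fpr <- round(pmin(pmax(fpr, 0), 1), 10)
  tpr <- round(pmin(pmax(tpr, 0), 1), 10)
  o <- order(fpr, tpr)
  list(fpr = c(0, fpr[o], 1), tpr = c(0, tpr[o], 1))
}

#' Time-dependent ROC AUC (cumulative/dynamic, Kaplan-Meier estimator)
#'
#' Cases are patients with an event by the horizon, controls those still
#' event-free; censoring is handled with Kaplan-Meier survival estimates
#' within the marker-positive / marker-negative strata (the classic
#' cumulative/dynamic construction, plain KM weighting without
#' nearest-neighbour smoothing). The AUC is the trapezoid over the ROC
#' points at every distinct marker cutoff; on uncensored data this equals
#' the Mann-Whitney rank statistic between cases and survivors. A percentile
#' bootstrap CI over patients is attached when `B_ci > 0`.
#'
#' @param marker risk marker (larger = higher risk).
#' @param time,status survival outcome (same units as `horizon`).
#' @param horizon evaluation time.
#' @param B_ci bootstrap repetitions for the CI (0 = none).
#' @param seed integer seed for the bootstrap.
#' @param conf.level CI level.
#' @return list: `auc`, `ci` (or NULL), `horizon`, `n_case_weight`.
#' @export
td_auc <- function(marker, time, status, horizon, B_ci = 1000, seed = 1L,
                   conf.level = 0.95) {
  assert_that(is.numeric(marker) && length(marker) == length(time),
              "marker must match time")
  assert_that(is_num1(horizon) && horizon > 0, "horizon must be > 0")
  if (horizon > max(time)) stop_input("horizon beyond observed follow-up")
  roc <- td_roc_points(marker, time, status, horizon)
  auc <- trapz(roc$fpr, roc$tpr)
  ci <- NULL
  if (B_ci > 0) {
    n <- length(marker)
    boots <- rep(NA_real_, B_ci)
    for (b in seq_len(B_ci)) {
      idx <- with_seed(derive_seed(seed, 60000 + b),
                       sample.int(n, n, replace = TRUE))
      boots[b] <- tryCatch({
        r <- td_roc_points(marker[idx], time[idx], status[idx], horizon)
        trapz(r$fpr, r$tpr)
      }, error = function(e) NA_real_)
    }
    boots <- boots[is.finite(boots)]
    a <- (1 - conf.level) / 2
    if (length(boots) >= 10)
      ci <- unname(quantile(boots, c(a, 1 - a)))
  }
  list(auc = auc, ci = ci, horizon = horizon,
       n_case_weight = 1 - km_surv_at(time, status, horizon))
}

## IPCW weights for a horizon: censoring distribution G by reversed KM
ipcw_weights <- function(time, status, horizon) {
  g_at <- function(tt) km_surv_at(time, 1 - status, tt)
  n <- length(time)
  w <- numeric(n)
  ind <- numeric(n)
  for (i in seq_len(n)) {
    if (time[i] <= horizon && status[i] == 1) {       # observed event by t
      w[i] <- 1 / max(g_at(time[i] - 1e-9), 1e-12)
      ind[i] <- 1
    } else if (time[i] > horizon) {                    # event-free past t
      w[i] <- 1 / max(g_at(horizon), 1e-12)
      ind[i] <- 0
    }                                                  # censored early: w = 0
  }
  list(w = w, ind = ind)
}

#' Calibration of predicted event risks at a fixed horizon
#'
#' Computes the inverse-probability-of-censoring-weighted (IPCW) Brier score
#' at the horizon, a binned calibration curve (mean predicted risk vs
#' KM-observed risk per risk-quantile bin), and a recalibration slope and
#' intercept: the slope is the Cox coefficient of the
#' complementary-log-log-transformed predicted risk
#' (`lp = log(-log(1 - risk))`; 1 = perfect), the intercept compares the
#' overall observed cloglog risk with the mean predicted one (0 = perfect).
#' When `refit_fun` is supplied, Harrell's bootstrap optimism correction is
#' applied to the slope and intercept (refit on each resample, evaluate on
#' the original data); otherwise percentile bootstrap CIs are reported.
#'
#' @param risk predicted event risks by the horizon, in (0, 1).
#' @param time,status survival outcome.
#' @param horizon evaluation time (same units as `time`).
#' @param B bootstrap repetitions.
#' @param bins number of calibration bins.
#' @param seed integer seed.
#' @param refit_fun optional `function(idx)` returning predicted risks for
#'   the *original* patients from a model refit on the bootstrap resample
#'   `idx` (enables optimism correction).
#' @return list: `brier`, `curve` (bin table), `intercept`, `slope`,
#'   `slope_defined`, `corrected` (optimism-corrected slope/intercept, if
#'   `refit_fun` given), `ci` (percentile CIs otherwise).
#' @export
calibration_at <- function(risk, time, status, horizon, B = 1000, bins = 5,
                           seed = 1L, refit_fun = NULL) {
  assert_that(all(risk > 0 & risk < 1), "risks must lie strictly in (0, 1)")
  assert_that(length(risk) == length(time), "risk must match time")
  ipw <- ipcw_weights(time, status, horizon)
  brier <- mean(ipw$w * (ipw$ind - risk)^2)

  qs <- unique(quantile(risk, probs = seq(0, 1, length.out = bins + 1)))
  bin <- if (length(qs) < 2) factor(rep("all", length(risk)))
         else cut(risk, breaks = qs, include.lowest = TRUE)
  curve <- do.call(rbind, lapply(levels(bin), function(lv) {
    i <- which(bin == lv)
    if (!length(i)) return(NULL)
    data.frame(bin = lv, n = length(i), predicted = mean(risk[i]),
               observed = 1 - km_surv_at(time[i], status[i], horizon))
  }))

  cal_fit <- function(risk, time, status) {
    lp <- log(-log(1 - risk))
    if (sd(lp) < 1e-12)
      return(list(slope = NA_real_, intercept = NA_real_, defined = FALSE))
    sl <- tryCatch(suppressWarnings(unname(coef(survival::coxph(
      survival::Surv(time, status) ~ lp))[1])), error = function(e) NA_real_)
    s_obs <- km_surv_at(time, status, horizon)
    ic <- if (s_obs > 0 && s_obs < 1)
      log(-log(s_obs)) - log(-log(1 - mean(risk))) else NA_real_
    list(slope = sl, intercept = ic, defined = is.finite(sl))
  }
  app <- cal_fit(risk, time, status)

  corrected <- NULL; ci <- NULL
  if (B > 0) {
    n <- length(risk)
    sl_b <- ic_b <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      idx <- with_seed(derive_seed(seed, 70000 + b),
                       sample.int(n, n, replace = TRUE))
      if (is.null(refit_fun)) {
        cb <- tryCatch(cal_fit(risk[idx], time[idx], status[idx]),
                       error = function(e) NULL)
        if (!is.null(cb)) { sl_b[b] <- cb$slope; ic_b[b] <- cb$intercept }
      } else {
        ## optimism: performance of the refit model on its resample minus on
        ## the original data
        rb <- tryCatch(refit_fun(idx), error = function(e) NULL)
        if (is.null(rb)) next
        on_boot <- tryCatch(cal_fit(rb$boot %||% risk[idx], time[idx],
                                    status[idx]), error = function(e) NULL)
        on_orig <- tryCatch(cal_fit(rb$orig, time, status),
                            error = function(e) NULL)
        if (!is.null(on_boot) && !is.null(on_orig)) {
          sl_b[b] <- on_boot$slope - on_orig$slope
          ic_b[b] <- on_boot$intercept - on_orig$intercept
        }
      }
    }
    if (is.null(refit_fun)) {
      ok <- is.finite(sl_b)
      if (sum(ok) >= 10)
        ci <- list(slope = unname(quantile(sl_b[ok], c(0.025, 0.975))),
                   intercept = unname(quantile(ic_b[is.finite(ic_b)],
                                               c(0.025, 0.975))))
    } else {
      corrected <- list(
        slope = app$slope - mean(sl_b[is.finite(sl_b)]),
        intercept = app$intercept - mean(ic_b[is.finite(ic_b)]))
    }
  }
  list(brier = brier, curve = curve, intercept = app$intercept,
       slope = app$slope, slope_defined = app$defined,
       corrected = corrected, ci = ci, horizon = horizon)
}

#' Decision-curve analysis for survival data
#'
#' For each risk threshold `pt`, net benefit
#' `NB = TP/n - FP/n * pt / (1 - pt)`, where the true/false positives among
#' test-positive patients (`risk >= pt`) are estimated from the Kaplan-Meier
#' event probability at the horizon within that subgroup. Treat-all uses the
#' whole cohort; treat-none is identically zero.
#'
#' @param risk predicted event risks by the horizon, in (0, 1).
#' @param time,status survival outcome.
#' @param horizon evaluation time.
#' @param thresholds risk threshold grid, strictly inside (0, 1).
#' @return data.frame: `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(risk, time, status, horizon,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  assert_that(length(thresholds) >= 1, "threshold grid must be non-empty")
  assert_that(all(thresholds > 0 & thresholds < 1),
              "thresholds must lie in (0, 1)")
  assert_that(length(risk) == length(time), "risk must match time")
  n <- length(risk)
  ev_all <- 1 - km_surv_at(time, status, horizon)
  out <- lapply(thresholds, function(pt) {
    odds <- pt / (1 - pt)
    pos <- risk >= pt
    if (any(pos)) {
      p_pos <- mean(pos)
      ev_pos <- 1 - km_surv_at(time[pos], status[pos], horizon)
      nb <- p_pos * ev_pos - p_pos * (1 - ev_pos) * odds
    } else nb <- 0
    data.frame(threshold = pt, nb_model = nb,
               nb_all = ev_all - (1 - ev_all) * odds, nb_none = 0)
  })
  do.call(rbind, out)
}
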