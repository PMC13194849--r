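## Single-feature risk stratification: Kaplan-Meier estimation, the two-group
## log-rank test, and the data-driven optimal log-rank cutpoint.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood-variance confidence intervals
#' (via [survival::survfit()]).
#'
#' @param time,status survival outcome (time > 0; 1 = event).
#' @param conf.level CI level.
#' @return data.frame: `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`.
#' @export
km_estimate <- function(time, status, conf.level = 0.95) {
  assert_that(length(time) >= 1 && length(time) == length(status),
              "need matching time/status, length >= 1")
  if (all(time <= 0)) stop_input("all survival times are <= 0")
  sf <- survival::survfit(survival::Surv(time, status) ~ 1,
                          conf.int = conf.level, conf.type = "log")
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv, lower = sf$lower, upper = sf$upper)
}

## KM survival probability at a single time point (fast internal path):
## vectorized product-limit over the event times up to `at`
km_surv_at <- function(time, status, at) {
  evt <- time[status == 1 & time <= at]
  if (!length(evt)) return(1)
  tab <- table(evt)
  tt <- as.numeric(names(tab))
  d <- as.vector(tab)
  st <- sort(time)
  # number at risk just before each event time
  r <- length(time) - findInterval(tt - 1e-12, st)
  prod(1 - d / r)
}

#' Two-group log-rank test
#'
#' @param time,status survival outcome.
#' @param group two-level grouping vector.
#' @return list: `statistic` (1-df chi-square), `p`, `obs`, `exp` (per
#'   group).
#' @export
logrank_test <- function(time, status, group) {
  g <- as.factor(group)
  assert_that(nlevels(droplevels(g)) == 2, "group must have exactly two non-empty levels")
  sd <- survival::survdiff(survival::Surv(time, status) ~ g)
  list(statistic = sd$chisq, p = pchisq(sd$chisq, 1, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}

#' Optimal log-rank cutpoint for a continuous marker
#'
#' Scans midpoints between consecutive sorted distinct marker values whose
#' induced groups each contain at least `min_group_frac` of the patients
#' (and at least 3 patients), and returns the cutoff maximizing the log-rank
#' chi-square. This search is data-driven and exploratory: the maximally
#' selected statistic inflates the type-I error of the associated p-value.
#'
#' @param marker numeric marker values (>= 2 distinct).
#' @param time,status survival outcome.
#' @param min_group_frac minimum fraction of patients in each group.
#' @return object of class `stratification_result`: `cutoff`, `statistic`,
#'   `p` (naive), `group` (factor `"low_marker"`/`"high_marker"`),
#'   `high_risk` (which side is high risk, by observed-minus-expected
#'   events), `km` (per-group [km_estimate()]), `n_cutoffs_scanned`.
#' @export
optimal_logrank_cutoff <- function(marker, time, status,
                                   min_group_frac = 0.15) {
  assert_that(is.numeric(marker) && length(marker) == length(time),
              "marker must be numeric, matching time")
  vals <- sort(unique(marker))
  if (length(vals) < 2) stop_input("no admissible cutoff: marker is constant")
  n <- length(marker)
  min_n <- max(3, ceiling(min_group_frac * n))
  cand <- (vals[-1] + vals[-length(vals)]) / 2
  cand <- cand[vapply(cand, function(cc)
    sum(marker <= cc) >= min_n && sum(marker > cc) >= min_n, logical(1))]
  if (!length(cand)) stop_input("no admissible cutoff under the group-size constraint")
  stats <- vapply(cand, function(cc) {
    g <- marker <= cc
    tryCatch(logrank_test(time, status, g)$statistic, error = function(e) NA_real_)
  }, numeric(1))
  if (all(!is.finite(stats))) stop_input("log-rank failed at every candidate cutoff")
  best <- which.max(stats)
  cutoff <- cand[best]
  g <- factor(ifelse(marker <= cutoff, "low_marker", "high_marker"),
              levels = c("low_marker", "high_marker"))
  lr <- logrank_test(time, status, g)
  ## the group with more observed than expected events is the high-risk side
  side <- levels(g)[which.max(lr$obs - lr$exp)]
  km <- lapply(split(seq_len(n), g), function(i)
    km_estimate(time[i], status[i]))
  structure(list(cutoff = cutoff, statistic = lr$statistic, p = lr$p,
                 group = g, high_risk = side, km = km,
                 n_cutoffs_scanned = length(cand)),
            class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf(paste0("<stratification: cutoff=%.5g, log-rank chi2=%.2f ",
                     "(naive p=%.3g), high-risk side: %s, %d cutoffs scanned>\n"),
              x$cutoff, x$statistic, x$p, x$high_risk, x$n_cutoffs_scanned))
  invisible(x)
}
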