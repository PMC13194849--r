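## Bootstrap-LASSO-Cox stable feature selection and multivariate Cox
## modelling. The penalized path and partial-likelihood machinery are
## delegated to glmnet and survival; fold construction, the lambda grid, the
## 1-SE choice, bootstrap aggregation and the optimism correction are owned
## here.

#' Configuration for stable feature selection
#'
#' @param B number of bootstrap resamples (default 1000).
#' @param folds cross-validation folds for the per-resample LASSO-Cox
#'   (default 5), event-stratified.
#' @param threshold stability threshold on the selection frequency (strict
#'   `>`, default 0.5).
#' @param n_lambda size of the log-spaced lambda grid (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of the all-zero
#'   lambda_max (default 1e-4, i.e. 4 decades).
#' @param seed integer seed.
#' @param retry_cap redraws of fold assignments when a fold has no events.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(B = 1000, folds = 5, threshold = 0.5,
                             n_lambda = 100, lambda_min_ratio = 1e-4,
                             seed = 1L, retry_cap = 10) {
  assert_that(is_count(B) && B >= 1, "B must be >= 1")
  assert_that(is_count(folds) && folds >= 2, "folds must be >= 2")
  assert_that(is_num1(threshold) && threshold > 0 && threshold < 1,
              "threshold must be in (0, 1)")
  structure(list(B = as.integer(B), folds = as.integer(folds),
                 threshold = threshold, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, seed = as.integer(seed),
                 retry_cap = retry_cap), class = "selection_config")
}

check_surv_input <- function(x, time, status) {
  assert_that(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  assert_that(!is.null(colnames(x)), "x must have column names")
  assert_that(length(time) == nrow(x) && length(status) == nrow(x),
              "time/status must match nrow(x)")
  assert_that(all(time > 0), "survival times must be positive")
  assert_that(all(status %in% c(0, 1)), "status must be 0/1")
}

## event-stratified, seeded fold assignment; retries until every fold holds
## at least one event (cap then error)
stratified_folds <- function(status, k, seed, retry_cap = 10) {
  n <- length(status)
  for (r in seq_len(retry_cap)) {
    foldid <- with_seed(derive_seed(seed, 500 + r), {
      f <- integer(n)
      ev <- sample(which(status == 1))
      ce <- sample(which(status == 0))
      f[ev] <- rep_len(seq_len(k), length(ev))
      f[ce] <- rep_len(seq_len(k), length(ce))
      f
    })
    if (all(tabulate(foldid[status == 1], k) > 0)) return(foldid)
  }
  stop_input("could not build folds with events in every fold (too few events)")
}

## z-score columns; constant columns are zeroed (never selectable)
standardize_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- Inf
  scale(x, center = mu, scale = ifelse(is.finite(sdv), sdv, 1)) *
    rep(ifelse(is.finite(sdv), 1, 0), each = nrow(x))
}

#' LASSO-Cox with cross-validated 1-SE lambda on one dataset
#'
#' Features are z-scored internally, an L1-penalized proportional-hazards
#' path is fit over a log-spaced lambda grid (4 decades down from the
#' all-zero `lambda_max`), lambda is chosen by the 1-SE rule on
#' cross-validated partial-likelihood deviance with event-stratified folds,
#' and the features with nonzero coefficients at that lambda are returned.
#'
#' @param x numeric feature matrix (patients x features, named columns).
#' @param time,status survival outcome (days; 1 = event).
#' @param config a [selection_config()].
#' @return character vector of selected feature names (possibly empty), with
#'   attributes `lambda` (chosen value) and `coef` (nonzero coefficients).
#' @export
lasso_cox_cv <- function(x, time, status, config = selection_config()) {
  check_surv_input(x, time, status)
  assert_that(sum(status) >= 2, "need at least 2 events")
  xs <- standardize_cols(x)
  y <- survival::Surv(time, status)
  ## glmnet warns when the path is truncated at very small lambda (benign:
  ## solutions for larger lambda are returned); keep the output quiet
  fit0 <- suppressWarnings(glmnet::glmnet(xs, y, family = "cox",
                                          standardize = FALSE, nlambda = 5))
  lmax <- fit0$lambda[1]
  grid <- exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
                  length.out = config$n_lambda))
  foldid <- stratified_folds(status, config$folds, config$seed,
                             config$retry_cap)
  cv <- suppressWarnings(
    glmnet::cv.glmnet(xs, y, family = "cox", standardize = FALSE,
                      lambda = grid, foldid = foldid, grouped = TRUE))
  cf <- as.matrix(coef(cv, s = "lambda.1se"))
  sel <- rownames(cf)[cf[, 1] != 0]
  attr(sel, "lambda") <- cv$lambda.1se
  attr(sel, "coef") <- cf[cf[, 1] != 0, 1]
  sel
}

#' Bootstrap-LASSO-Cox selection frequencies
#'
#' Patients are resampled with replacement `B` times; [lasso_cox_cv()] runs
#' on each resample; per-feature selection frequencies are
#' (times selected)/B, and the stable set is every feature with frequency
#' strictly greater than `config$threshold`. Resamples on which the
#' penalized fit is infeasible (e.g. too few events) select nothing and are
#' counted in `n_failed`.
#'
#' @inheritParams lasso_cox_cv
#' @return object of class `selection_result`: data.frame `freq` (feature,
#'   frequency, stable), `stable` (character), `B`, `n_failed`.
#' @export
bootstrap_selection <- function(x, time, status, config = selection_config()) {
  check_surv_input(x, time, status)
  n <- nrow(x)
  counts <- setNames(numeric(ncol(x)), colnames(x))
  n_failed <- 0L
  for (b in seq_len(config$B)) {
    idx <- with_seed(derive_seed(config$seed, 10000 + b),
                     sample.int(n, n, replace = TRUE))
    cfg_b <- config
    cfg_b$seed <- derive_seed(config$seed, 20000 + b)
    sel <- tryCatch(
      lasso_cox_cv(x[idx, , drop = FALSE], time[idx], status[idx], cfg_b),
      error = function(e) NULL)
    if (is.null(sel)) n_failed <- n_failed + 1L
    else counts[sel] <- counts[sel] + 1
  }
  freq <- counts / config$B
  df <- data.frame(feature = names(freq), frequency = as.numeric(freq),
                   stable = as.numeric(freq) > config$threshold,
                   row.names = NULL)
  df <- df[order(-df$frequency, df$feature), ]
  rownames(df) <- NULL
  structure(list(freq = df, stable = df$feature[df$stable],
                 B = config$B, n_failed = n_failed,
                 threshold = config$threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: B=%d (%d failed), stable (freq > %.2f): %s>\n",
              x$B, x$n_failed, x$threshold,
              if (length(x$stable)) paste(x$stable, collapse = ", ") else "none"))
  print(head(x$freq, 10))
  invisible(x)
}

#' Multivariate Cox proportional-hazards model
#'
#' Maximum partial likelihood with Efron tie handling on z-scored features;
#' Wald confidence intervals, hazard ratios, and a likelihood-ratio test
#' against the null model. Separation / non-convergence is flagged as an
#' error rather than returned silently.
#'
#' @param x numeric feature matrix (named columns); z-scored internally
#'   unless `standardize = FALSE`.
#' @param time,status survival outcome.
#' @param standardize z-score the features first (default TRUE).
#' @param conf.level Wald CI level.
#' @param strict error on non-convergence/separation (default TRUE). With
#'   `strict = FALSE` the fit is returned with `converged = FALSE` instead —
#'   used by rank-based consumers such as the C-index, for which a monotone
#'   likelihood is harmless.
#' @return object of class `bmk_cox`: `table` (coef, se, z, p, HR and CIs
#'   per covariate), `loglik`, `lr_stat`, `lr_df`, `lr_p`, `concordance`,
#'   `n`, `n_event`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(x, time, status, standardize = TRUE, conf.level = 0.95,
                    strict = TRUE) {
  check_surv_input(x, time, status)
  assert_that(ncol(x) >= 1, "feature subset must be non-empty")
  if (sum(status) < ncol(x))
    warning("fewer events than covariates; estimates will be unstable")
  xs <- if (standardize) standardize_cols(x) else x
  df <- data.frame(xs, check.names = FALSE)
  df$.time <- time; df$.status <- status
  fml <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                 paste(sprintf("`%s`", colnames(x)),
                                       collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron", x = TRUE),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w))) {
        if (strict)
          stop_input("Cox model failed to converge (possible separation): ",
                     conditionMessage(w))
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(coef(fit))) ||
      (strict && any(abs(coef(fit)) > 20)))
    stop_input("Cox model failed to converge (possible separation)")
  s <- summary(fit, conf.int = conf.level)
  zq <- stats::qnorm(1 - (1 - conf.level) / 2)
  cf <- coef(fit); se <- sqrt(diag(fit$var))
  tab <- data.frame(feature = names(cf), coef = unname(cf), se = unname(se),
                    coef_lo = unname(cf - zq * se), coef_hi = unname(cf + zq * se),
                    hr = exp(unname(cf)),
                    hr_lo = exp(unname(cf - zq * se)),
                    hr_hi = exp(unname(cf + zq * se)),
                    z = unname(cf / se),
                    p = unname(2 * stats::pnorm(-abs(cf / se))),
                    row.names = NULL)
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  structure(list(table = tab, loglik = fit$loglik,
                 lr_stat = lr, lr_df = length(cf),
                 lr_p = pchisq(lr, length(cf), lower.tail = FALSE),
                 concordance = unname(s$concordance["C"]),
                 n = fit$n, n_event = fit$nevent, fit = fit,
                 standardize = standardize, converged = converged),
            class = "bmk_cox")
}

#' @export
print.bmk_cox <- function(x, ...) {
  cat(sprintf("<bmk_cox: n=%d, events=%d, C=%.3f, LR chi2=%.2f (df=%d, p=%.3g)>\n",
              x$n, x$n_event, x$concordance, x$lr_stat, x$lr_df, x$lr_p))
  print(x$table, digits = 3)
  invisible(x)
}

#' Optimism-corrected Harrell C-index
#'
#' Harrell's bootstrap procedure: the model is refit on each resample; the
#' optimism is the resample C-index minus the C-index of that fit's linear
#' predictor on the original data; the corrected C is the apparent C minus
#' the mean optimism. A percentile CI over the per-resample corrected values
#' is attached.
#'
#' @inheritParams fit_cox
#' @param B bootstrap repetitions (default 1000).
#' @param seed integer seed.
#' @param conf.level CI level.
#' @return list: `apparent`, `corrected`, `optimism`, `ci`, `B`, `n_failed`.
#' @export
optimism_corrected_cindex <- function(x, time, status, B = 1000, seed = 1L,
                                      conf.level = 0.95) {
  assert_that(is_count(B) && B >= 1, "B must be >= 1")
  base <- fit_cox(x, time, status, strict = FALSE)
  apparent <- base$concordance
  n <- nrow(x)
  y <- survival::Surv(time, status)
  opt <- rep(NA_real_, B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- with_seed(derive_seed(seed, 40000 + b),
                     sample.int(n, n, replace = TRUE))
    fb <- tryCatch(fit_cox(x[idx, , drop = FALSE], time[idx], status[idx],
                           strict = FALSE),
                   error = function(e) NULL)
    if (is.null(fb)) { n_failed <- n_failed + 1L; next }
    c_boot <- fb$concordance
    ## evaluate the bootstrap model's linear predictor on the original data,
    ## using the bootstrap standardization (moments travel with the model)
    mu <- colMeans(x[idx, , drop = FALSE])
    sdv <- apply(x[idx, , drop = FALSE], 2, sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    lp <- as.vector(scale(x, center = mu, scale = sdv) %*%
                      coef(fb$fit))
    c_orig <- tryCatch(
      survival::concordance(y ~ lp, reverse = TRUE)$concordance,
      error = function(e) NA_real_)
    if (!is.finite(c_orig)) { n_failed <- n_failed + 1L; next }
    opt[b] <- c_boot - c_orig
  }
  opt <- opt[is.finite(opt)]
  if (!length(opt)) stop_input("all bootstrap repetitions failed")
  corrected <- apparent - mean(opt)
  a <- (1 - conf.level) / 2
  list(apparent = apparent, corrected = corrected, optimism = mean(opt),
       ci = unname(quantile(apparent - opt, c(a, 1 - a))),
       B = B, n_failed = n_failed)
}

#' Proportional-hazards test on Schoenfeld residuals
#'
#' Score test of scaled Schoenfeld residuals against transformed time
#' (via [survival::cox.zph()]), per covariate plus a global test.
#'
#' @param model a [fit_cox()] result (or a `coxph` fit).
#' @param transform time transform passed to `cox.zph` (default `"km"`).
#' @return data.frame with columns `term`, `chisq`, `df`, `p`; the last row
#'   is the global test.
#' @export
ph_test <- function(model, transform = "km") {
  fit <- if (inherits(model, "bmk_cox")) model$fit else model
  assert_that(inherits(fit, "coxph"), "model must be a bmk_cox or coxph fit")
  if (length(coef(fit)) == 0) stop_input("model has no covariates")
  z <- survival::cox.zph(fit, transform = transform)
  tab <- as.data.frame(z$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}
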