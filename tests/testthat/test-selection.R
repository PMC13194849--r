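# bootstrap-LASSO-Cox selection, Cox modelling, optimism correction, PH test

make_sel_data <- function(n = 200, beta = -2.3, seed = 1, p_noise = 10) {
  set.seed(seed)
  x <- matrix(rnorm(n * (p_noise + 1)), n, p_noise + 1,
              dimnames = list(NULL, c("signal", paste0("noise", seq_len(p_noise)))))
  tt <- rexp(n, 0.002 * exp(beta * scale(x[, 1])[, 1]))
  cc <- runif(n, 0, 2000)
  list(x = x, time = pmin(tt, cc), status = as.integer(tt <= cc))
}

test_that("lasso_cox_cv finds a strong signal and little under the null", {
  d <- make_sel_data(seed = 101)
  sel <- lasso_cox_cv(d$x, d$time, d$status, selection_config(seed = 1))
  expect_true("signal" %in% sel)

  # under the null the 1-SE selection stays small on average
  sizes <- vapply(1:10, function(s) {
    dn <- make_sel_data(beta = 0, seed = 200 + s)
    length(lasso_cox_cv(dn$x, dn$time, dn$status, selection_config(seed = s)))
  }, numeric(1))
  expect_lte(mean(sizes), 2)
})

test_that("selection frequency is invariant to column order and affine rescaling", {
  d <- make_sel_data(n = 120, seed = 7)
  cfg <- selection_config(B = 25, seed = 5)
  base <- bootstrap_selection(d$x, d$time, d$status, cfg)

  perm <- sample(ncol(d$x))
  reord <- bootstrap_selection(d$x[, perm], d$time, d$status, cfg)
  expect_equal(base$freq$frequency[order(base$freq$feature)],
               reord$freq$frequency[order(reord$freq$feature)])

  x2 <- d$x
  x2[, "signal"] <- 1000 * x2[, "signal"] - 37
  resc <- bootstrap_selection(x2, d$time, d$status, cfg)
  expect_equal(base$freq, resc$freq)
})

test_that("bootstrap_selection: B = 1 yields 0/1 frequencies and seeds reproduce", {
  d <- make_sel_data(n = 100, seed = 3)
  r1 <- bootstrap_selection(d$x, d$time, d$status, selection_config(B = 1, seed = 2))
  expect_true(all(r1$freq$frequency %in% c(0, 1)))

  cfg <- selection_config(B = 10, seed = 9)
  a <- bootstrap_selection(d$x, d$time, d$status, cfg)
  b <- bootstrap_selection(d$x, d$time, d$status, cfg)
  expect_identical(a$freq, b$freq)
  expect_error(selection_config(B = 0), "B")
})

test_that("fit_cox: coef/HR identity, null LR, closed-form exponential oracle", {
  d <- make_sel_data(n = 150, seed = 11)
  m <- fit_cox(d$x[, 1:3], d$time, d$status)
  expect_equal(m$table$hr, exp(m$table$coef), tolerance = 1e-12)
  # Table-3-style printed pair: coef -2.30 corresponds to HR 0.10
  expect_equal(exp(-2.30), 0.10, tolerance = 0.005)

  # two-group exponential survival, no censoring: log-HR ~ log rate ratio
  set.seed(21)
  g <- rep(0:1, each = 500)
  tt <- c(rexp(500, 0.001), rexp(500, 0.003))
  mg <- fit_cox(matrix(g, ncol = 1, dimnames = list(NULL, "g")), tt,
                rep(1L, 1000), standardize = FALSE)
  truth <- log(3)
  expect_gt(truth, mg$table$coef_lo[1])
  expect_lt(truth, mg$table$coef_hi[1])
})

test_that("Cox partial likelihood matches the brute-force risk-set oracle (n <= 8)", {
  # hand-enumerable datasets, with and without ties
  datasets <- list(
    list(x = c(0.5, -1, 2, 0, 1, -0.5), time = c(3, 5, 7, 2, 8, 4),
         status = c(1, 0, 1, 1, 0, 1)),
    list(x = c(1, 1, -1, 0, 2, -2, 0.5, 0), time = c(2, 2, 3, 3, 5, 6, 6, 7),
         status = c(1, 1, 1, 0, 1, 1, 1, 0)))
  for (d in datasets) {
    xm <- matrix(d$x, ncol = 1, dimnames = list(NULL, "x"))
    m <- fit_cox(xm, d$time, d$status, standardize = FALSE)
    beta <- m$table$coef[1]
    expect_equal(m$fit$loglik[2],
                 oracle_cox_loglik(beta, xm, d$time, d$status),
                 tolerance = 1e-8)
    # and at an arbitrary beta via coxph's init/iter=0 evaluation
    f0 <- survival::coxph(survival::Surv(d$time, d$status) ~ x,
                          data = data.frame(x = d$x),
                          init = 0.3, control = survival::coxph.control(iter.max = 0))
    expect_equal(f0$loglik[2], oracle_cox_loglik(0.3, xm, d$time, d$status),
                 tolerance = 1e-8)
  }
})

test_that("optimism correction: apparent perfection, shrinkage, null behaviour", {
  # perfectly ranking marker, no censoring: apparent C = 1
  n <- 40
  x <- matrix(seq_len(n) + 0, ncol = 1, dimnames = list(NULL, "m"))
  time <- rev(seq_len(n)) + 0
  res <- optimism_corrected_cindex(x, time, rep(1L, n), B = 20, seed = 1)
  expect_equal(res$apparent, 1.0)

  # overfit: 10 noise covariates at n = 40 shrink the corrected C
  set.seed(31)
  xo <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(NULL, paste0("v", 1:10)))
  to <- rexp(40, 0.01)
  ro <- optimism_corrected_cindex(xo, to, rep(1L, 40), B = 40, seed = 2)
  expect_lt(ro$corrected, ro$apparent)
  expect_error(optimism_corrected_cindex(xo, to, rep(1L, 40), B = 0), "B")
})

test_that("ph_test: calibrated under PH, powered against crossing hazards, degenerate error", {
  d <- make_sel_data(n = 150, seed = 41)
  m <- fit_cox(d$x[, 1:2], d$time, d$status)
  tab <- ph_test(m)
  expect_identical(tab$term[nrow(tab)], "GLOBAL")
  expect_true(all(tab$p >= 0 & tab$p <= 1))

  # crossing hazards: binary covariate whose effect reverses over time
  set.seed(42)
  n <- 500
  g <- rep(0:1, each = n / 2)
  tt <- ifelse(g == 1,
               ifelse(runif(n / 2) < 0.5, rexp(n / 2, 0.05), 5 + rexp(n / 2, 0.002)),
               rexp(n / 2, 0.01))
  mph <- fit_cox(matrix(g, ncol = 1, dimnames = list(NULL, "g")), tt,
                 rep(1L, n), standardize = FALSE)
  expect_lt(ph_test(mph)$p[1], 0.05)

  null_fit <- survival::coxph(survival::Surv(d$time, d$status) ~ 1)
  expect_error(ph_test(null_fit), "covariates")
})
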