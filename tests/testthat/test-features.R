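# TAC feature operators and feature-vector assembly

test_that("roi_mean_tac averages voxel curves exactly", {
  tt <- seq(0, 10, by = 1)
  a <- tac_curve(tt, rep(0, 11))
  b <- tac_curve(tt, rep(2, 11))
  m <- roi_mean_tac(list(a, b))
  expect_equal(m$values, rep(1, 11))

  one <- tac_curve(tt, sin(tt) + 2)
  expect_equal(roi_mean_tac(list(one, one, one))$values, one$values)

  set.seed(1)
  vox <- lapply(1:50, function(i) tac_curve(tt, runif(11)))
  got <- roi_mean_tac(vox)$values
  oracle <- sapply(seq_along(tt), function(j)
    sum(vapply(vox, function(v) v$values[j], numeric(1))) / 50)
  expect_equal(got, oracle)

  expect_error(roi_mean_tac(list(a, tac_curve(tt + 0.5, rep(1, 11)))), "grid")
})

test_that("tac_value_at interpolates linearly and guards its range", {
  cv <- tac_curve(c(0, 2, 4), c(1, 3, 2))
  expect_equal(tac_value_at(cv, 2), 3)
  expect_equal(tac_value_at(cv, 1), 2)     # midpoint of (1, 3)
  expect_equal(tac_value_at(cv, 3), 2.5)
  expect_error(tac_value_at(cv, 5), "support")

  # dense analytic curve: value at tau = 10 within 0.5 %
  tt <- seq(0, 20, by = 0.1)
  f <- function(t) 5 * exp(-0.11 * t) + 0.3 * t
  cv2 <- tac_curve(tt, f(tt))
  expect_equal(tac_value_at(cv2, 10), f(10), tolerance = 5e-3)
})

test_that("slope_between: constants, affine identity, sign convention", {
  tt <- seq(0, 40, by = 0.5)
  expect_equal(slope_between(tac_curve(tt, rep(4, length(tt)))), 0)

  aff <- tac_curve(tt, 2 + 0.37 * tt)
  expect_equal(slope_between(aff, 10, 30), 0.37, tolerance = 1e-12)
  expect_equal(slope_between(aff, 5, 12), 0.37, tolerance = 1e-12)

  # declining curve between 10 and 30 min must give a NEGATIVE slope (the
  # convention that makes the bone-marrow cutoff value negative)
  dec <- tac_curve(tt, 10 * exp(-0.05 * tt))
  expect_lt(slope_between(dec, 10, 30), 0)
})

test_that("auc_t equals the brute-force trapezoid accumulation and is linear", {
  expect_equal(auc_t(tac_curve(c(0, 1), c(0, 2))), 1)
  tt <- seq(0, 65, length.out = 28)
  expect_equal(auc_t(tac_curve(tt, rep(3, 28))), 3 * 65)

  set.seed(2)
  v1 <- runif(28); v2 <- runif(28)
  oracle <- 0
  for (i in 1:27) oracle <- oracle + (v1[i] + v1[i + 1]) / 2 * (tt[i + 1] - tt[i])
  expect_equal(auc_t(tac_curve(tt, v1)), oracle)
  expect_equal(auc_t(tac_curve(tt, v1 + v2)),
               auc_t(tac_curve(tt, v1)) + auc_t(tac_curve(tt, v2)),
               tolerance = 1e-12)
})

test_that("peak_features: closed forms, ties, degenerate peaks", {
  # tent: 0 at t=0 up to 4 at t=20, back down; covers 60
  tt <- c(0, 20, 60)
  tent <- tac_curve(tt, c(0, 4, 0))
  pf <- peak_features(tent)
  expect_equal(pf[["TAC_max"]], 4)
  expect_equal(pf[["Time_TM"]], 20)
  expect_equal(pf[["Slope_0_max"]], 0.2)
  expect_equal(pf[["Slope_max_60"]], (0 - 4) / 40)

  # monotone increasing: peak at last sample; slope to 60 defined as 0
  inc <- tac_curve(seq(0, 65, by = 5), seq(0, 65, by = 5) * 0.1)
  pfi <- peak_features(inc)
  expect_equal(pfi[["Time_TM"]], 65)
  expect_equal(pfi[["Slope_max_60"]], 0)

  # peak at first sample: pre-peak slope defined as 0
  dec <- tac_curve(seq(0, 65, by = 5), exp(-0.1 * seq(0, 65, by = 5)))
  expect_equal(peak_features(dec)[["Slope_0_max"]], 0)

  # tie: earliest attaining time wins
  tie <- tac_curve(c(0, 10, 20, 60), c(0, 5, 5, 1))
  expect_equal(peak_features(tie)[["Time_TM"]], 10)

  expect_error(peak_features(tac_curve(c(0, 10, 30), c(0, 5, 3))), "60")
})

test_that("feature operators are stable under denser resampling", {
  tt28 <- default_frame_schedule()$mid_min
  f <- function(t) 8 * (exp(-0.05 * t) - exp(-0.6 * t))
  coarse <- tac_curve(tt28, f(tt28))
  dense <- tac_curve(seq(min(tt28), max(tt28), length.out = 2000),
                     f(seq(min(tt28), max(tt28), length.out = 2000)))
  expect_equal(slope_between(coarse), slope_between(dense), tolerance = 5e-3)
  expect_equal(auc_t(coarse) / auc_t(dense), 1, tolerance = 5e-3)
  pk_c <- peak_features(coarse); pk_d <- peak_features(dense)
  expect_equal(pk_c[["TAC_max"]] / pk_d[["TAC_max"]], 1, tolerance = 5e-3)
})

test_that("extract_feature_vector: frozen names, counts, zero curves", {
  nm <- kinetic_feature_names()
  expect_length(nm, 28)
  expect_equal(sum(startsWith(nm, "T_")), 14)
  expect_equal(sum(startsWith(nm, "BM_")), 14)
  # golden contract for the canonical ordering
  expect_identical(nm[1:6], c("T_Cf_Slope_10_30", "T_Cf_AUC_T",
                              "T_Cf_Slope_0_max", "T_Cf_Slope_max_60",
                              "T_Cf_Time_TM", "T_Cf_TAC_max"))
  expect_identical(nm[13:14], c("T_Cm_Slope_0_max", "T_Cm_TAC_max"))
  expect_true("BM_Cf_Slope_10_30" %in% nm)   # the BCS biomarker

  tt <- default_frame_schedule()$mid_min
  zero <- tac_curve(tt, rep(0, 28))
  dec <- list(cb = zero, cf = zero, cm = zero)
  fv <- extract_feature_vector(dec, dec)
  expect_identical(names(fv), nm)
  # every slope / AUC / max feature is 0 (Time_TM is a time, not an amplitude)
  expect_true(all(fv[!grepl("Time_TM", names(fv))] == 0))

  expect_error(extract_feature_vector(list(cb = zero, cf = zero), dec), "cm")
})

test_that("fitted BCS tracks the generator's true slope under low noise", {
  co <- gen_cohort(cohort_spec(n_patients = 12, noise_level = 0.02, seed = 31))
  f <- cohort_features(co, fit_options(n_grid_starts = 2, n_jitter_starts = 1))
  expect_gt(cor(f$BM_Cf_Slope_10_30, co$slopes), 0.9)
})

test_that("conventional_features matches phantom truths", {
  cf <- conventional_features(rep(3, 10), rep(1.2, 5), 1)
  expect_equal(cf[["MTV"]], 10)
  expect_equal(cf[["TLG"]], 30)
  expect_equal(cf[["BM_SUVmean"]], 1.2)

  cf0 <- conventional_features(rep(2, 10), rep(1, 5), 1)
  expect_equal(cf0[["MTV"]], 0)
  expect_equal(cf0[["TLG"]], 0)

  set.seed(3)
  vox <- runif(400, 0, 6)
  cfr <- conventional_features(vox, vox / 4, 0.5)
  expect_equal(cfr[["MTV"]], sum(vox >= 2.5) * 0.5)
  expect_equal(cfr[["TLG"]], cfr[["MTV"]] * mean(vox[vox >= 2.5]))
  expect_true(cfr[["T_SUVmin"]] <= cfr[["T_SUVmean"]] &&
                cfr[["T_SUVmean"]] <= cfr[["T_SUVmax"]])
  expect_error(conventional_features(numeric(0), 1, 1), "empty")
})
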