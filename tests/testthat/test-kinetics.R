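# 2TC forward model, frame averaging, fitting and decomposition

test_that("model_curves: trivial regimes behave as the compartment structure demands", {
  input <- quick_input(step = 0.05)
  tt <- seq(0, 65, by = 0.5)

  # K1 = 0: no uptake, tissue signal is pure blood volume
  mc0 <- model_curves(kinetic_params(0, 0.3, 0.05, 0, 0.08), input, tt)
  expect_equal(mc0$cf$values, rep(0, length(tt)))
  expect_equal(mc0$cm$values, rep(0, length(tt)))
  expect_equal(mc0$ct$values, 0.08 * mc0$cb$values, tolerance = 1e-12)

  # k4 = 0: irreversible trapping, C_m non-decreasing
  mc1 <- model_curves(kinetic_params(0.15, 0.4, 0.08, 0, 0.05), input, tt)
  expect_true(all(diff(mc1$cm$values) >= -1e-12))

  # decomposition identity pointwise
  p <- kinetic_params(0.2, 0.5, 0.06, 0.004, 0.1)
  mc2 <- model_curves(p, input, tt)
  expect_equal((1 - p$vb) * (mc2$cf$values + mc2$cm$values) + p$vb * mc2$cb$values,
               mc2$ct$values, tolerance = 1e-12)
})

test_that("model_curves with k3 = k4 = 0 matches the independent convolution oracle", {
  # C_f reduces to K1 exp(-k2 t) (x) C_b; oracle: Richardson trapezoid
  p <- kinetic_params(0.2, 0.45, 0, 0, 0)
  t_end <- 20
  h <- 0.01
  tt <- seq(0, t_end, by = h)
  input <- gen_input_function(aif_params(), tt)
  mc <- model_curves(p, input, tt)
  cb_fun <- approxfun(tt, input$values)
  y <- oracle_conv(function(s) p$K1 * exp(-p$k2 * s), cb_fun, t_end, h = h)
  pk <- max(mc$cf$values)
  expect_lt(max(abs(mc$cf$values - y)) / pk, 1e-6)
  expect_equal(max(abs(mc$cm$values)), 0)
})

test_that("model_curves matches the RK4 ODE oracle for general parameters", {
  tt <- seq(0, 65, by = 0.01)
  input <- gen_input_function(aif_params(), tt)
  for (p in list(kinetic_params(0.1, 0.2, 0.02, 0, 0.05),
                 kinetic_params(0.3, 0.8, 0.15, 0.02, 0.2))) {
    mc <- model_curves(p, input, tt)
    ok <- oracle_rk4_2tc(p, tt, input$values)
    pk <- max(mc$ct$values)
    expect_lt(max(abs(mc$cf$values - ok$cf)) / pk, 1e-6)
    expect_lt(max(abs(mc$cm$values - ok$cm)) / pk, 1e-6)
  }
})

test_that("model_curves validates its inputs", {
  input <- quick_input()
  p <- kinetic_params(0.1, 0.3, 0.05)
  expect_error(model_curves(p, input, seq(0, 100, by = 1)), "cover")
  expect_error(model_curves(p, input, c(1, 1, 2)), "increasing")
})

test_that("frame_average: constant, linear and cubic curves", {
  sched <- default_frame_schedule()
  tt <- seq(0, 65, by = 0.25)

  cst <- tac_curve(tt, rep(3.7, length(tt)))
  expect_equal(frame_average(cst, sched), rep(3.7, 28))

  lin <- tac_curve(tt, 0.4 + 0.2 * tt)
  expect_equal(frame_average(lin, sched), 0.4 + 0.2 * sched$mid_min,
               tolerance = 1e-12)

  # cubic: compare with high-resolution quadrature of the same interpolant
  cub <- tac_curve(tt, 1 + 0.05 * tt - 0.002 * tt^2 + 1e-5 * tt^3)
  got <- frame_average(cub, sched)
  oracle <- vapply(seq_len(28), function(i) {
    a <- sched$start_s[i] / 60; b <- sched$end_s[i] / 60
    g <- seq(a, b, length.out = 4001)
    v <- approx(tt, cub$values, g)$y
    sum((v[-1] + v[-length(v)]) / 2 * diff(g)) / (b - a)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-3)

  expect_error(frame_average(tac_curve(c(0, 10), c(1, 1)), sched), "support")
})

test_that("default schedule is the 28-frame 65-min protocol", {
  sched <- default_frame_schedule()
  expect_length(sched$mid_min, 28)
  expect_equal(sched$end_s[28], 3900)
  expect_equal(sum(sched$dur_min), 65)
})

test_that("fit_2tc recovers noise-free parameters and flags degenerate input", {
  input <- quick_input(step = 0.02)
  sched <- default_frame_schedule()
  truth <- kinetic_params(0.14, 0.42, 0.07, 0, 0.09)
  fr <- frame_average(model_curves(truth, input, seq(0, 65, by = 0.02))$ct, sched)
  fit <- fit_2tc(fr, input, sched, fit_options(fix_k4 = TRUE))
  expect_true(fit$converged)
  for (nm in c("K1", "k2", "k3", "vb"))
    expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)

  # vb = 0 curve: estimated vb stays at the boundary
  t0 <- kinetic_params(0.12, 0.35, 0.06, 0, 0)
  fr0 <- frame_average(model_curves(t0, input, seq(0, 65, by = 0.02))$ct, sched)
  fit0 <- fit_2tc(fr0, input, sched, fit_options(fix_k4 = TRUE))
  expect_lte(fit0$params$vb, 0.02)

  expect_error(fit_2tc(rep(0, 28), input, sched), "degenerate")
})

test_that("decompose returns components satisfying the model identity", {
  input <- quick_input(step = 0.02)
  sched <- default_frame_schedule()
  truth <- kinetic_params(0.18, 0.5, 0.08, 0, 0.07)
  fr <- frame_average(model_curves(truth, input, seq(0, 65, by = 0.02))$ct, sched)
  fit <- fit_2tc(fr, input, sched, fit_options(fix_k4 = TRUE))
  dec <- decompose(fit)
  p <- fit$params
  lhs <- (1 - p$vb) * (dec$cf$values + dec$cm$values) + p$vb * dec$cb$values
  expect_lt(max(abs(lhs - fit$ct$values)) / max(abs(fit$ct$values)), 1e-9)

  fit$converged <- FALSE
  expect_error(decompose(fit), "non-converged")
})

test_that("WRSS never increases with more restarts", {
  set.seed(42)
  input <- quick_input(step = 0.05)
  sched <- default_frame_schedule()
  truth <- kinetic_params(0.1, 0.3, 0.05, 0, 0.06)
  fr0 <- frame_average(model_curves(truth, input, seq(0, 65, by = 0.05))$ct, sched)
  fr <- fr0 + rnorm(28, 0, 0.05 * mean(fr0))
  w1 <- fit_2tc(fr, input, sched,
                fit_options(n_grid_starts = 1, n_jitter_starts = 0))$wrss
  w12 <- fit_2tc(fr, input, sched,
                 fit_options(n_grid_starts = 8, n_jitter_starts = 4))$wrss
  expect_lte(w12, w1 + 1e-12)
})
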