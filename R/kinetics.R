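## Two-tissue compartment (2TC) kinetics: containers, forward model, frame
## averaging, weighted NLS fitting, and TAC decomposition.
##
## Compartment structure: blood C_b exchanges with free tissue tracer C_f
## (rates K1, k2); C_f is phosphorylated to the trapped pool C_m (k3) and
## dephosphorylated back (k4). The measured tissue concentration is
##   C_T(t) = (1 - v_b) (C_f(t) + C_m(t)) + v_b C_b(t).

#' Time-activity curve container
#'
#' A minimal container for a sampled time-activity curve (TAC): strictly
#' increasing sample times in minutes and activity values in kBq/mL.
#'
#' @param times numeric vector of sample times (minutes), strictly increasing.
#' @param values numeric vector of activity values (kBq/mL), same length.
#' @param component label, one of `"measured"`, `"blood"`, `"free"`,
#'   `"metabolized"`, `"model"`.
#' @return an object of class `tac_curve` (list with `times`, `values`,
#'   `component`).
#' @export
tac_curve <- function(times, values,
                      component = c("measured", "blood", "free",
                                    "metabolized", "model")) {
  component <- match.arg(component)
  assert_that(is.numeric(times) && is.numeric(values), "times/values must be numeric")
  assert_that(length(times) == length(values), "times and values lengths differ")
  assert_that(length(times) >= 2, "a tac_curve needs at least 2 samples")
  assert_that(all(is.finite(times)) && all(is.finite(values)),
              "times and values must be finite")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  structure(list(times = as.double(times), values = as.double(values),
                 component = component), class = "tac_curve")
}

#' @export
print.tac_curve <- function(x, ...) {
  cat(sprintf("<tac_curve: %s, %d samples, t = [%.3g, %.3g] min, peak %.4g kBq/mL>\n",
              x$component, length(x$times), x$times[1],
              x$times[length(x$times)], max(x$values)))
  invisible(x)
}

#' Two-tissue compartment rate constants
#'
#' @param K1 blood-to-tissue transport (mL/min/mL), `>= 0`.
#' @param k2 tissue-to-blood efflux (1/min), `>= 0`.
#' @param k3 phosphorylation rate (1/min), `>= 0`.
#' @param k4 dephosphorylation rate (1/min), `>= 0` (0 = irreversible model).
#' @param vb fractional blood volume, in `[0, 1)`.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3, k4 = 0, vb = 0.05) {
  for (nm in c("K1", "k2", "k3", "k4", "vb")) {
    v <- get(nm)
    assert_that(is_num1(v), nm, " must be a finite scalar")
  }
  assert_that(K1 >= 0 && k2 >= 0 && k3 >= 0 && k4 >= 0,
              "rate constants must be non-negative")
  assert_that(vb >= 0 && vb < 1, "vb must lie in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vb = vb),
            class = "kinetic_params")
}

#' Dynamic frame schedule
#'
#' Contiguous, strictly increasing dynamic-PET frames given by start and end
#' times in seconds from scan start. The default schedule is 28 frames over
#' 65 min: 6 x 10 s, 4 x 30 s, 4 x 60 s, 4 x 120 s, 10 x 300 s (3900 s).
#'
#' @param start_s,end_s frame start/end times (seconds).
#' @return object of class `frame_schedule` with fields `start_s`, `end_s`,
#'   `mid_min` (frame mid-times, minutes), `dur_min`.
#' @export
frame_schedule <- function(start_s, end_s) {
  assert_that(length(start_s) == length(end_s) && length(start_s) >= 1,
              "start_s/end_s must be equal-length, non-empty")
  assert_that(all(end_s > start_s), "each frame must have end > start")
  assert_that(all(abs(start_s[-1] - end_s[-length(end_s)]) < 1e-9),
              "frames must be contiguous and non-overlapping")
  assert_that(all(start_s >= 0), "frame times must be non-negative")
  structure(list(start_s = as.double(start_s), end_s = as.double(end_s),
                 mid_min = (start_s + end_s) / 120,
                 dur_min = (end_s - start_s) / 60),
            class = "frame_schedule")
}

#' @rdname frame_schedule
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(10, 6), rep(30, 4), rep(60, 4), rep(120, 4), rep(300, 10))
  ends <- cumsum(dur)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

## eigenvalues/weights of the 2TC impulse response. With
## s = k2 + k3 + k4 the eigenvalues are a12 = (s -/+ sqrt(s^2 - 4 k2 k4))/2 and
##   Cf = K1 [ (k4 - a1) E1 + (a2 - k4) E2 ] / (a2 - a1)
##   Cm = K1 k3 (E1 - E2) / (a2 - a1),    Ei = exp(-ai t) (x) Cb.
tc2_eigen <- function(p) {
  k2 <- p$k2; k3 <- p$k3; k4 <- p$k4
  s <- k2 + k3 + k4
  d <- sqrt(max(s * s - 4 * k2 * k4, 0))
  if (d < 1e-9) {            # near-degenerate eigenvalues: nudge k3
    k3 <- k3 + 1e-7
    s <- k2 + k3 + k4
    d <- sqrt(max(s * s - 4 * k2 * k4, 0))
  }
  a1 <- (s - d) / 2
  a2 <- (s + d) / 2
  list(a1 = a1, a2 = a2,
       bf1 = (k4 - a1) / d, bf2 = (a2 - k4) / d, bm = k3 / d)
}

## core forward model on a grid where `cb` is interpreted piecewise-linearly;
## exact (to machine precision) for that interpolant via the exponential
## integrator in conv_exp_lin().
tc2_components <- function(p, t, cb) {
  if (p$K1 == 0) {
    z <- numeric(length(t))
    return(list(cf = z, cm = z))
  }
  eg <- tc2_eigen(p)
  e1 <- conv_exp_lin(t, cb, eg$a1)
  e2 <- conv_exp_lin(t, cb, eg$a2)
  list(cf = p$K1 * (eg$bf1 * e1 + eg$bf2 * e2),
       cm = p$K1 * eg$bm * (e1 - e2))
}

#' Forward 2TC model component curves
#'
#' Solves the two-tissue compartment system
#' \deqn{dC_f/dt = K_1 C_b - (k_2 + k_3) C_f + k_4 C_m, \quad
#'       dC_m/dt = k_3 C_f - k_4 C_m}
#' with zero initial conditions, for a blood input curve treated as piecewise
#' linear between its samples, and returns `C_f`, `C_m` and the model tissue
#' curve `C_T = (1 - v_b)(C_f + C_m) + v_b C_b` at the requested times.
#' The solution is an exponential-integrator evaluation of the analytic
#' impulse response, exact for the piecewise-linear input.
#'
#' @param p a [kinetic_params()] object.
#' @param input a [tac_curve()] with the blood input function `C_b`.
#' @param times evaluation times (minutes), strictly increasing, within the
#'   input curve's support.
#' @return list of `tac_curve`s: `cf`, `cm`, `ct` (model), `cb` (input at
#'   `times`).
#' @export
model_curves <- function(p, input, times) {
  assert_that(inherits(p, "kinetic_params"), "p must be kinetic_params")
  assert_that(inherits(input, "tac_curve"), "input must be a tac_curve")
  assert_that(is.numeric(times) && length(times) >= 2 && all(diff(times) > 0),
              "times must be strictly increasing, length >= 2")
  if (min(times) < input$times[1] - 1e-9 ||
      max(times) > input$times[length(input$times)] + 1e-9)
    stop_input("input grid does not cover the requested times")
  ## union grid keeps the piecewise-linear input exact at its own breakpoints
  keep <- input$times > min(times) & input$times < max(times)
  grid <- sort(unique(c(times, input$times[keep], min(times))))
  ## solution must start at t where C is 0; prepend the input origin so the
  ## zero initial condition is anchored at the start of the input support
  if (grid[1] > input$times[1]) grid <- c(input$times[1], grid)
  cb <- interp_lin(input$times, input$values, grid)
  comp <- tc2_components(p, grid, cb)
  idx <- match(times, grid)
  cb_t <- cb[idx]
  cf <- comp$cf[idx]
  cm <- comp$cm[idx]
  ct <- (1 - p$vb) * (cf + cm) + p$vb * cb_t
  list(cf = tac_curve(times, cf, "free"),
       cm = tac_curve(times, cm, "metabolized"),
       ct = tac_curve(times, ct, "model"),
       cb = tac_curve(times, cb_t, "blood"))
}

#' Frame-average a curve over a dynamic schedule
#'
#' Each frame value is the time integral of the (piecewise-linear) curve over
#' the frame divided by the frame duration, computed by trapezoid on a
#' sub-grid that includes the curve's own sample points (hence exact for
#' piecewise-linear curves).
#'
#' @param curve a [tac_curve()] covering the schedule span.
#' @param schedule a [frame_schedule()].
#' @param n_sub minimum number of sub-intervals per frame.
#' @return numeric vector of per-frame mean values.
#' @export
frame_average <- function(curve, schedule, n_sub = 8) {
  assert_that(inherits(curve, "tac_curve"), "curve must be a tac_curve")
  assert_that(inherits(schedule, "frame_schedule"), "schedule must be a frame_schedule")
  s_min <- schedule$start_s / 60
  e_min <- schedule$end_s / 60
  if (s_min[1] < curve$times[1] - 1e-9 ||
      e_min[length(e_min)] > curve$times[length(curve$times)] + 1e-9)
    stop_input("frame outside curve support")
  vapply(seq_along(s_min), function(i) {
    inside <- curve$times > s_min[i] & curve$times < e_min[i]
    pts <- sort(unique(c(seq(s_min[i], e_min[i], length.out = n_sub + 1),
                         curve$times[inside])))
    v <- interp_lin(curve$times, curve$values, pts)
    trapz(pts, v) / (e_min[i] - s_min[i])
  }, numeric(1))
}

## dense evaluation grid for fitting: sub-samples each frame (finer early)
fit_eval_grid <- function(schedule, step_min = 0.05, max_sub = 12) {
  s <- schedule$start_s / 60; e <- schedule$end_s / 60
  pts <- unlist(lapply(seq_along(s), function(i) {
    n <- min(max_sub, max(2, ceiling((e[i] - s[i]) / step_min)))
    seq(s[i], e[i], length.out = n + 1)
  }))
  sort(unique(pts))
}

#' Fitting options for [fit_2tc()]
#'
#' @param fix_k4 logical; fix `k4 = 0` (irreversible model) instead of
#'   estimating it within its bound.
#' @param lower,upper parameter bounds, named `K1, k2, k3, k4, vb`. Defaults:
#'   K1, k2 in \[0, 2\], k3 in \[0, 1\], k4 in \[0, 0.05\], vb in \[0, 0.3\]
#'   (physiologic FDG ranges; the k4 cap prevents exchange-rate blowup on
#'   flat marrow curves).
#' @param n_grid_starts number of fixed coarse-grid starts (max 8).
#' @param n_jitter_starts number of additional seeded random starts.
#' @param seed seed for the jittered starts.
#' @param maxit optimizer iteration cap per start.
#' @return list of options.
#' @export
fit_options <- function(fix_k4 = FALSE,
                        lower = c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, vb = 0),
                        upper = c(K1 = 2, k2 = 2, k3 = 1, k4 = 0.05, vb = 0.3),
                        n_grid_starts = 8, n_jitter_starts = 4,
                        seed = 1L, maxit = 300) {
  list(fix_k4 = isTRUE(fix_k4), lower = lower, upper = upper,
       n_grid_starts = n_grid_starts, n_jitter_starts = n_jitter_starts,
       seed = seed, maxit = maxit)
}

#' Fit the 2TC model to a measured frame TAC
#'
#' Bounded weighted nonlinear least squares: the model tissue curve is
#' frame-averaged over the schedule and compared to the measured frame values
#' with weights proportional to frame duration (a count-rate surrogate).
#' Multi-start: a fixed coarse grid of initial values plus seeded jittered
#' starts; the best weighted residual sum of squares (WRSS) wins, ties broken
#' by lower k4.
#'
#' @param measured numeric vector of measured frame values (one per frame) or
#'   a `tac_curve` sampled at the frame mid-times.
#' @param input blood input [tac_curve()] covering the scan.
#' @param schedule a [frame_schedule()].
#' @param options a [fit_options()] list.
#' @return object of class `bmk_fit`: `params` ([kinetic_params()]),
#'   `wrss`, `converged`, `n_restarts`, component curves at frame mid-times
#'   (`cf`, `cm`, `cb`, `ct`), fitted frame means `fitted_frames`, and the
#'   schedule.
#' @export
fit_2tc <- function(measured, input, schedule, options = fit_options()) {
  if (inherits(measured, "tac_curve")) measured <- measured$values
  assert_that(is.numeric(measured) && length(measured) == length(schedule$mid_min),
              "measured must have one value per frame")
  if (all(measured <= 0) || sum(measured > 0) < length(measured) / 4)
    stop_input("degenerate measured TAC (all-zero or negative-dominated)")
  assert_that(inherits(input, "tac_curve"), "input must be a tac_curve")

  grid <- fit_eval_grid(schedule)
  if (grid[1] < input$times[1] - 1e-9 ||
      grid[length(grid)] > input$times[length(input$times)] + 1e-9)
    stop_input("input does not cover the scan span")
  cb <- interp_lin(input$times, input$values, grid)
  w <- schedule$dur_min / sum(schedule$dur_min)
  s_min <- schedule$start_s / 60; e_min <- schedule$end_s / 60
  ## precompute per-frame trapezoid weights over the fixed grid so each
  ## objective evaluation is two convolutions plus a matrix product
  fw <- frame_weights(grid, s_min, e_min)

  free <- c("K1", "k2", "k3", if (!options$fix_k4) "k4", "vb")
  lo <- options$lower[free]; hi <- options$upper[free]

  obj <- function(theta) {
    p <- as.list(theta)
    if (options$fix_k4) p$k4 <- 0
    comp <- tc2_components(p, grid, cb)
    ct <- (1 - p$vb) * (comp$cf + comp$cm) + p$vb * cb
    fr <- as.vector(fw %*% ct)
    sum(w * (measured - fr)^2)
  }

  g <- expand.grid(K1 = c(0.05, 0.4), k2 = c(0.1, 0.6), k3 = c(0.02, 0.2))
  starts <- lapply(seq_len(min(nrow(g), options$n_grid_starts)), function(i) {
    st <- c(K1 = g$K1[i], k2 = g$k2[i], k3 = g$k3[i], k4 = 0.002, vb = 0.05)
    st[free]
  })
  if (options$n_jitter_starts > 0) {
    jit <- with_seed(derive_seed(options$seed, 17), {
      lapply(seq_len(options$n_jitter_starts), function(i)
        setNames(lo + runif(length(free)) * (hi - lo) * 0.5, free))
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    res <- tryCatch(
      optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = min(options$maxit, 60), factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    k4v <- if (options$fix_k4) 0 else res$par[["k4"]]
    if (is.null(best) || res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && k4v < best$k4)) {
      best <- res; best$k4 <- k4v
    }
  }
  if (is.null(best)) stop_input("2TC fit failed from every start")
  ## polish the winner
  pol <- tryCatch(
    optim(best$par, obj, method = "L-BFGS-B", lower = lo, upper = hi,
          control = list(maxit = max(options$maxit, 500), factr = 1e4)),
    error = function(e) NULL)
  if (!is.null(pol)) {
    if (pol$convergence == 0) any_conv <- TRUE
    if (pol$value <= best$value) { best$par <- pol$par; best$value <- pol$value }
  }

  th <- as.list(best$par)
  if (options$fix_k4) th$k4 <- 0
  p <- kinetic_params(th$K1, th$k2, th$k3, th$k4, th$vb)
  mid <- schedule$mid_min
  mc <- model_curves(p, input, sort(unique(c(grid, mid))))
  idx <- match(mid, mc$ct$times)
  comp_grid <- tc2_components(p, grid, cb)
  ct_grid <- (1 - p$vb) * (comp_grid$cf + comp_grid$cm) + p$vb * cb
  structure(list(
    params = p,
    wrss = best$value,
    converged = any_conv,
    n_restarts = length(starts),
    cf = tac_curve(mid, mc$cf$values[idx], "free"),
    cm = tac_curve(mid, mc$cm$values[idx], "metabolized"),
    cb = tac_curve(mid, mc$cb$values[idx], "blood"),
    ct = tac_curve(mid, mc$ct$values[idx], "model"),
    fitted_frames = as.vector(fw %*% ct_grid),
    measured = measured,
    schedule = schedule), class = "bmk_fit")
}

## matrix F (n_frames x n_grid) with F %*% v = per-frame trapezoid means
frame_weights <- function(grid, s_min, e_min) {
  n <- length(grid)
  out <- matrix(0, length(s_min), n)
  for (i in seq_along(s_min)) {
    j <- which(grid >= s_min[i] - 1e-12 & grid <= e_min[i] + 1e-12)
    tt <- grid[j]
    wts <- numeric(length(j))
    dt <- diff(tt)
    wts[-length(j)] <- wts[-length(j)] + dt / 2
    wts[-1] <- wts[-1] + dt / 2
    out[i, j] <- wts / (e_min[i] - s_min[i])
  }
  out
}

#' @export
print.bmk_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<bmk_fit: K1=%.4f k2=%.4f k3=%.4f k4=%.4f vb=%.4f | ",
                     "WRSS=%.4g, converged=%s, %d starts>\n"),
              p$K1, p$k2, p$k3, p$k4, p$vb, x$wrss, x$converged, x$n_restarts))
  invisible(x)
}

#' Decompose a fitted TAC into blood, free and metabolized components
#'
#' Returns the input-function samples and the model-derived free and
#' metabolized curves at the frame mid-times, as used for feature extraction.
#' The algebraic identity `(1 - vb)(C_f + C_m) + vb C_b == model C_T` holds
#' at every midpoint.
#'
#' @param fit a converged [fit_2tc()] result.
#' @return list of three `tac_curve`s: `cb`, `cf`, `cm`.
#' @export
decompose <- function(fit) {
  assert_that(inherits(fit, "bmk_fit"), "fit must be a bmk_fit")
  if (!isTRUE(fit$converged))
    stop_input("cannot decompose a non-converged fit")
  list(cb = fit$cb, cf = fit$cf, cm = fit$cm)
}
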