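## Fully synthetic dynamic-PET cohorts with known ground truth: a Feng-style
## tri-exponential bolus input function, 2TC tissue kinetics for tumor and
## bone-marrow ROIs on the 28-frame/65-min schedule, frame-duration-dependent
## Gaussian noise, and progression-free survival whose hazard depends
## log-linearly on the (standardized) bone-marrow free-FDG 10-30 min slope.

#' Arterial input function parameters (tri-exponential bolus)
#'
#' Feng-style form, for `s = t - t0 >= 0`:
#' \deqn{C_b(t) = (A_1 s - A_2 - A_3) e^{-\lambda_1 s} + A_2 e^{-\lambda_2 s}
#'       + A_3 e^{-\lambda_3 s}}
#' and 0 before the arrival delay `t0`. Requires
#' `lambda1 > lambda2 > lambda3 >= 0` and non-negative `A2`, `A3`, `t0`,
#' which makes the curve non-negative with a single early peak.
#'
#' @param A1 bolus amplitude (kBq/mL/min).
#' @param A2,A3 tail amplitudes (kBq/mL).
#' @param lambda1,lambda2,lambda3 decay rates (1/min), strictly decreasing.
#' @param t0 arrival delay (min).
#' @return object of class `aif_params`.
#' @export
aif_params <- function(A1 = 300, A2 = 3, A3 = 2.5,
                       lambda1 = 4, lambda2 = 0.5, lambda3 = 0.01,
                       t0 = 0.1) {
  for (nm in c("A1", "A2", "A3", "lambda1", "lambda2", "lambda3", "t0"))
    assert_that(is_num1(get(nm)), nm, " must be a finite scalar")
  assert_that(lambda1 > lambda2 && lambda2 > lambda3 && lambda3 >= 0,
              "require lambda1 > lambda2 > lambda3 >= 0")
  assert_that(A2 >= 0 && A3 >= 0, "A2 and A3 must be non-negative")
  assert_that(A1 >= 0, "A1 must be non-negative")
  assert_that(t0 >= 0, "t0 must be non-negative")
  structure(list(A1 = A1, A2 = A2, A3 = A3, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3, t0 = t0),
            class = "aif_params")
}

#' Evaluate the blood input function on a time grid
#'
#' @param p an [aif_params()] object.
#' @param times strictly increasing, non-negative times (minutes).
#' @return a blood [tac_curve()] (zero before `t0`, non-negative).
#' @export
gen_input_function <- function(p, times) {
  assert_that(inherits(p, "aif_params"), "p must be aif_params")
  assert_that(is.numeric(times) && length(times) >= 2, "times must be numeric, length >= 2")
  if (any(diff(times) <= 0) || any(times < 0))
    stop_input("times must be strictly increasing and non-negative")
  s <- times - p$t0
  v <- ifelse(s < 0, 0,
              (p$A1 * s - p$A2 - p$A3) * exp(-p$lambda1 * s) +
                p$A2 * exp(-p$lambda2 * s) + p$A3 * exp(-p$lambda3 * s))
  tac_curve(times, pmax(v, 0), "blood")
}

#' Default kinetic-parameter priors per ROI
#'
#' Uniform sampling ranges for each 2TC parameter, chosen as physiologic FDG
#' ranges: a moderately avid NSCLC tumor and low-uptake vertebral bone
#' marrow.
#'
#' @return named list (`tumor`, `bone_marrow`) of 2-row range matrices.
#' @export
default_kinetic_priors <- function() {
  rng <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("K1", "k2", "k3", "k4", "vb")
    rownames(m) <- c("lo", "hi")
    m
  }
  list(tumor = rng(c(0.08, 0.20, 0.04, 0.000, 0.03),
                   c(0.25, 0.60, 0.12, 0.008, 0.15)),
       bone_marrow = rng(c(0.04, 0.15, 0.010, 0.000, 0.02),
                         c(0.12, 0.50, 0.050, 0.005, 0.10)))
}

#' Synthetic cohort specification
#'
#' @param n_patients cohort size (>= 2 for a cohort; [simulate_patient()]
#'   accepts any valid spec).
#' @param effect_size log hazard ratio per 1 SD of the true bone-marrow free
#'   (C_f) 10-30 min slope. Default -2.3/SD (a steeper, more negative slope
#'   raises the hazard).
#' @param baseline_hazard baseline event rate (events/day). The default
#'   0.00187 was produced by [calibrate_baseline_hazard()] for an expected
#'   event fraction of 17/32 under this default spec.
#' @param censor_admin_time administrative censoring time (days).
#' @param censor_unif_max upper bound of the independent uniform censoring
#'   draw (days); censoring time is `min(censor_admin_time, U(0, censor_unif_max))`.
#' @param priors kinetic parameter sampling ranges, see
#'   [default_kinetic_priors()].
#' @param noise_level fractional frame-noise scale (approximate relative
#'   error of a typical frame); 0 = noiseless.
#' @param aif an [aif_params()] object shared by the cohort.
#' @param schedule a [frame_schedule()].
#' @param seed integer seed; all randomness derives from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 32, effect_size = -2.3,
                        baseline_hazard = 0.00187, censor_admin_time = 900,
                        censor_unif_max = 2 * censor_admin_time,
                        priors = default_kinetic_priors(),
                        noise_level = 0.05,
                        aif = aif_params(),
                        schedule = default_frame_schedule(),
                        seed = 1L) {
  assert_that(is_count(n_patients), "n_patients must be a non-negative integer")
  assert_that(n_patients >= 2, "n_patients must be >= 2")
  assert_that(is_num1(baseline_hazard) && baseline_hazard > 0,
              "baseline_hazard must be > 0")
  assert_that(is_num1(noise_level) && noise_level >= 0,
              "noise_level must be >= 0")
  assert_that(is_num1(censor_admin_time) && censor_admin_time > 0,
              "censor_admin_time must be > 0")
  assert_that(is_num1(censor_unif_max) && censor_unif_max > 0,
              "censor_unif_max must be > 0")
  assert_that(is.list(priors) && all(c("tumor", "bone_marrow") %in% names(priors)),
              "priors must list tumor and bone_marrow ranges")
  for (roi in c("tumor", "bone_marrow")) {
    m <- priors[[roi]]
    assert_that(is.matrix(m) && nrow(m) == 2 &&
                  all(colnames(m) == c("K1", "k2", "k3", "k4", "vb")),
                "priors$", roi, " must be a 2 x 5 range matrix (K1,k2,k3,k4,vb)")
    assert_that(all(m["lo", ] <= m["hi", ]) && all(m["lo", ] >= 0) &&
                  m["hi", "vb"] < 1,
                "priors$", roi, " ranges must be valid kinetic_params bounds")
  }
  structure(list(n_patients = as.integer(n_patients), effect_size = effect_size,
                 baseline_hazard = baseline_hazard,
                 censor_admin_time = censor_admin_time,
                 censor_unif_max = censor_unif_max, priors = priors,
                 noise_level = noise_level, aif = aif, schedule = schedule,
                 seed = as.integer(seed)), class = "cohort_spec")
}

## dense grid used for "true" component curves (covers 0..scan end)
truth_grid <- function(schedule) {
  end <- schedule$end_s[length(schedule$end_s)] / 60
  sort(unique(c(seq(0, 2, by = 0.02), seq(2, end, by = 0.25))))
}

draw_kinetic_params <- function(prior) {
  u <- runif(5)
  v <- prior["lo", ] + u * (prior["hi", ] - prior["lo", ])
  kinetic_params(v[["K1"]], v[["k2"]], v[["k3"]], v[["k4"]], v[["vb"]])
}

## true (noiseless, continuous) bone-marrow C_f slope over 10-30 min
true_cf_slope <- function(p, input) {
  mc <- model_curves(p, input, seq(0, 31, by = 0.1))
  slope_between(mc$cf, 10, 30)
}

#' Reference moments of the true bone-marrow C_f slope under the priors
#'
#' Seeded Monte-Carlo estimate of the mean and SD of the true bone-marrow
#' free-component 10-30 min slope implied by `spec$priors`; used by
#' [simulate_patient()] to standardize the slope when no cohort is available.
#'
#' @param spec a [cohort_spec()].
#' @param n_mc Monte-Carlo draws.
#' @return named numeric `c(mean =, sd =)`.
#' @export
slope_reference <- function(spec, n_mc = 400) {
  input <- gen_input_function(spec$aif, truth_grid(spec$schedule))
  sl <- with_seed(derive_seed(spec$seed, 101), {
    vapply(seq_len(n_mc), function(i)
      true_cf_slope(draw_kinetic_params(spec$priors$bone_marrow), input),
      numeric(1))
  })
  c(mean = mean(sl), sd = sd(sl))
}

## frame noise: sd_i = noise_level * sqrt(C_i * C_ref * dt_ref / dt_i) with
## C_ref the mean positive frame value and dt_ref the mean frame duration,
## i.e. variance proportional to value / duration.
frame_noise_sd <- function(frames, dur_min, noise_level) {
  cref <- mean(frames[frames > 0])
  if (!is.finite(cref) || cref <= 0) cref <- 1
  dref <- mean(dur_min)
  noise_level * sqrt(pmax(frames, 0) * cref * dref / dur_min)
}

#' Simulate one synthetic patient
#'
#' Draws 2TC parameters for the tumor and bone-marrow ROIs from the priors,
#' frame-averages the model tissue curves over the schedule, adds zero-mean
#' Gaussian noise with variance proportional to value/frame-duration (scaled
#' by `noise_level`), and draws a progression-free survival time from an
#' exponential distribution with hazard
#' `baseline_hazard * exp(effect_size * z)`, where `z` is the standardized
#' true bone-marrow C_f slope over 10-30 min. Censoring is
#' `min(censor_admin_time, U(0, censor_unif_max))`.
#'
#' @param spec a [cohort_spec()].
#' @param patient_id identifier stored in the outputs.
#' @param slope_ref optional `c(mean, sd)` used to standardize the slope;
#'   default [slope_reference()] moments under the priors.
#' @param seed seed for this patient's draws (default derived from the spec
#'   seed and `patient_id`).
#' @return list with `params` (per ROI), `true_curves` (dense C_f/C_m/C_T per
#'   ROI), `frames` (measured per-frame values per ROI), `noiseless_frames`,
#'   `slope` (raw true bone-marrow C_f slope), `z`, and `survival`
#'   (`pfs_days`, `event`).
#' @export
simulate_patient <- function(spec, patient_id = 1L, slope_ref = NULL,
                             seed = derive_seed(spec$seed, patient_id)) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  if (is.null(slope_ref)) slope_ref <- slope_reference(spec)
  assert_that(length(slope_ref) == 2 && slope_ref[2] > 0,
              "slope_ref must be c(mean, sd) with sd > 0")
  grid <- truth_grid(spec$schedule)
  input <- gen_input_function(spec$aif, grid)
  with_seed(seed, {
    rois <- list()
    for (roi in c("tumor", "bone_marrow")) {
      p <- draw_kinetic_params(spec$priors[[roi]])
      mc <- model_curves(p, input, grid)
      fr0 <- frame_average(mc$ct, spec$schedule)
      sdv <- frame_noise_sd(fr0, spec$schedule$dur_min, spec$noise_level)
      fr <- fr0 + if (spec$noise_level > 0) rnorm(length(fr0), 0, sdv) else 0
      rois[[roi]] <- list(params = p, curves = mc,
                          noiseless_frames = fr0, frames = fr)
    }
    slope <- slope_between(rois$bone_marrow$curves$cf, 10, 30)
    z <- (slope - slope_ref[[1]]) / slope_ref[[2]]
    h <- spec$baseline_hazard * exp(spec$effect_size * z)
    t_event <- rexp(1, rate = h)
    cens <- min(spec$censor_admin_time, runif(1, 0, spec$censor_unif_max))
    list(patient_id = patient_id,
         params = lapply(rois, `[[`, "params"),
         true_curves = lapply(rois, `[[`, "curves"),
         noiseless_frames = lapply(rois, `[[`, "noiseless_frames"),
         frames = lapply(rois, `[[`, "frames"),
         input = input, slope = slope, z = z, true_hazard = h,
         survival = list(pfs_days = min(t_event, cens),
                         event = as.integer(t_event <= cens)))
  })
}

## light-path patient draw: reproduces simulate_patient's RNG consumption up
## to the bone-marrow parameter draw, computing only the true C_f slope
sim_patient_slope <- function(spec, patient_id, input_sub) {
  with_seed(derive_seed(spec$seed, patient_id), {
    draw_kinetic_params(spec$priors$tumor)          # parity with full path
    if (spec$noise_level > 0) rnorm(length(spec$schedule$mid_min))
    p <- draw_kinetic_params(spec$priors$bone_marrow)
    mc <- model_curves(p, input_sub, input_sub$times)
    slope_between(mc$cf, 10, 30)
  })
}

#' Generate a full synthetic cohort
#'
#' Runs [simulate_patient()] for each patient, then re-standardizes the true
#' bone-marrow C_f slope *within the cohort* and redraws survival from the
#' within-cohort z (the marker-hazard coupling the generator guarantees).
#' Also attaches simple clinical covariates (age, sex, smoking, stage) drawn
#' independently of outcome, and voxel SUV phantoms for conventional
#' features. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param tacs logical; if `FALSE`, skip storing per-patient TAC tables and
#'   phantoms (fast path for survival-only experiments).
#' @return object of class `bmk_cohort`: `tac` (long data.frame: patient_id,
#'   roi, frame_start_s, frame_end_s, activity_kbq_per_ml, including the
#'   `blood` input sampled at frame mid-times), `survival` (data.frame),
#'   `truth` (per-patient list: params, slope, z, true log-hazard), `input`
#'   (dense blood curve), `phantoms`, `spec`.
#' @export
gen_cohort <- function(spec, tacs = TRUE) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  if (tacs) {
    sref <- slope_reference(spec)
    pats <- lapply(seq_len(spec$n_patients), function(i)
      simulate_patient(spec, patient_id = i, slope_ref = sref))
    slopes <- vapply(pats, `[[`, numeric(1), "slope")
  } else {
    tg <- truth_grid(spec$schedule)
    input_sub <- gen_input_function(spec$aif, tg[tg <= 30])
    pats <- NULL
    slopes <- vapply(seq_len(spec$n_patients), function(i)
      sim_patient_slope(spec, i, input_sub), numeric(1))
  }
  sdev <- sd(slopes)
  z <- if (sdev > 0) (slopes - mean(slopes)) / sdev else rep(0, length(slopes))

  surv <- with_seed(derive_seed(spec$seed, 7001), {
    h <- spec$baseline_hazard * exp(spec$effect_size * z)
    t_event <- rexp(spec$n_patients, rate = h)
    cens <- pmin(spec$censor_admin_time,
                 runif(spec$n_patients, 0, spec$censor_unif_max))
    age <- round(rnorm(spec$n_patients, 56, 10), 1)
    sex <- sample(c("male", "female"), spec$n_patients, replace = TRUE)
    smoking <- sample(c(0L, 1L), spec$n_patients, replace = TRUE, prob = c(0.75, 0.25))
    stage <- sample(c("IIIB", "IVA", "IVB"), spec$n_patients, replace = TRUE,
                    prob = c(0.15, 0.35, 0.5))
    data.frame(patient_id = seq_len(spec$n_patients), age = age, sex = sex,
               smoking = smoking, stage = stage,
               pfs_days = pmin(t_event, cens),
               event = as.integer(t_event <= cens))
  })

  tac <- NULL
  phantoms <- NULL
  if (tacs) {
    sched <- spec$schedule
    input_mid <- interp_lin(pats[[1]]$input$times, pats[[1]]$input$values,
                            sched$mid_min)
    tac <- do.call(rbind, lapply(pats, function(pt) {
      do.call(rbind, lapply(c("tumor", "bone_marrow"), function(roi) {
        data.frame(patient_id = pt$patient_id, roi = roi,
                   frame_start_s = sched$start_s, frame_end_s = sched$end_s,
                   activity_kbq_per_ml = pt$frames[[roi]])
      }))
    }))
    blood <- do.call(rbind, lapply(pats, function(pt)
      data.frame(patient_id = pt$patient_id, roi = "blood",
                 frame_start_s = sched$start_s, frame_end_s = sched$end_s,
                 activity_kbq_per_ml = input_mid)))
    tac <- rbind(tac, blood)
    tac <- tac[order(tac$patient_id, tac$roi, tac$frame_start_s), ]
    rownames(tac) <- NULL
    phantoms <- with_seed(derive_seed(spec$seed, 9001), {
      lapply(seq_len(spec$n_patients), function(i)
        list(tumor = gen_voxel_phantom(60, 0.0207,
               suv = function(n) pmax(rnorm(n, 7, 3), 0.2)),
             bone_marrow = gen_voxel_phantom(120, 0.0207,
               suv = function(n) pmax(rnorm(n, 1.6, 0.4), 0.1))))
    })
  }

  truth <- lapply(seq_len(spec$n_patients), function(i) {
    list(patient_id = i, params = if (tacs) pats[[i]]$params,
         slope = slopes[i], z = z[i],
         log_hazard = log(spec$baseline_hazard) + spec$effect_size * z[i])
  })
  structure(list(tac = tac, survival = surv, truth = truth,
                 input = if (tacs) pats[[1]]$input else
                   gen_input_function(spec$aif, truth_grid(spec$schedule)),
                 phantoms = phantoms, spec = spec,
                 z = z, slopes = slopes),
            class = "bmk_cohort")
}

#' @export
print.bmk_cohort <- function(x, ...) {
  cat(sprintf("<bmk_cohort: n=%d, events=%d, effect=%.3g/SD, seed=%d>\n",
              nrow(x$survival), sum(x$survival$event),
              x$spec$effect_size, x$spec$seed))
  invisible(x)
}

#' Calibrate the baseline hazard to a target expected event fraction
#'
#' Monte-Carlo + root finding: draws standardized marker values `z` from the
#' kinetic priors' implied bone-marrow slope distribution (the distribution
#' the generator actually couples the hazard to) and censoring times from
#' the spec's censoring model, then solves for the baseline hazard whose
#' expected event fraction `E[1 - exp(-h0 e^{beta z} C)]` equals
#' `target_frac`.
#'
#' @param spec a [cohort_spec()].
#' @param target_frac target expected fraction of events (default 17/32).
#' @param n_mc Monte-Carlo draws.
#' @return calibrated baseline hazard (events/day).
#' @export
calibrate_baseline_hazard <- function(spec, target_frac = 17 / 32,
                                      n_mc = 2000) {
  assert_that(is_num1(target_frac) && target_frac > 0 && target_frac < 1,
              "target_frac must be in (0, 1)")
  input <- gen_input_function(spec$aif, truth_grid(spec$schedule))
  draws <- with_seed(derive_seed(spec$seed, 3301), {
    sl <- vapply(seq_len(n_mc), function(i)
      true_cf_slope(draw_kinetic_params(spec$priors$bone_marrow), input),
      numeric(1))
    list(z = (sl - mean(sl)) / sd(sl),
         cens = pmin(spec$censor_admin_time,
                     runif(n_mc, 0, spec$censor_unif_max)))
  })
  f <- function(log_h0) {
    h <- exp(log_h0) * exp(spec$effect_size * draws$z)
    mean(1 - exp(-h * draws$cens)) - target_frac
  }
  exp(uniroot(f, c(log(1e-8), log(1)), tol = 1e-10)$root)
}

#' Voxel SUV phantom with closed-form MTV/TLG truth
#'
#' @param n_voxels number of voxels (>= 1).
#' @param voxel_volume_mL volume of one voxel (mL, > 0).
#' @param suv SUV assignment rule: a scalar (uniform phantom), a numeric
#'   vector of length `n_voxels`, or a `function(n)` returning `n` draws.
#' @param threshold SUV threshold defining the metabolic volume (default 2.5).
#' @param seed optional seed applied around a stochastic `suv` function.
#' @return list: `suv`, `voxel_volume_mL`, and `truth` (`mtv_mL`, `tlg`,
#'   `n_above`) computed by exhaustive voxel counting.
#' @export
gen_voxel_phantom <- function(n_voxels, voxel_volume_mL, suv = 3.0,
                              threshold = 2.5, seed = NULL) {
  assert_that(is_count(n_voxels) && n_voxels >= 1, "n_voxels must be >= 1")
  assert_that(is_num1(voxel_volume_mL) && voxel_volume_mL > 0,
              "voxel_volume_mL must be > 0")
  vals <- if (is.function(suv)) {
    if (!is.null(seed)) with_seed(seed, suv(n_voxels)) else suv(n_voxels)
  } else if (length(suv) == 1) rep(as.double(suv), n_voxels) else as.double(suv)
  assert_that(length(vals) == n_voxels && all(is.finite(vals)),
              "suv rule must yield n_voxels finite values")
  above <- vals >= threshold
  mtv <- sum(above) * voxel_volume_mL
  tlg <- if (any(above)) mtv * mean(vals[above]) else 0
  list(suv = vals, voxel_volume_mL = voxel_volume_mL,
       truth = list(mtv_mL = mtv, tlg = tlg, n_above = sum(above)))
}
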