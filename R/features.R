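## TAC feature operators and feature-vector assembly.
##
## Six operators per component curve: Slope_10_30 (rise-over-run between the
## 10- and 30-min anchors, so a declining curve gives a NEGATIVE value),
## AUC_T (trapezoid over the whole curve), Slope_0_max, Slope_max_60,
## Time_TM (earliest time attaining the peak), TAC_max. For the metabolized
## component only Slope_0_max and TAC_max are kept (its growth is monotone),
## giving 14 features per ROI: 6 (C_f) + 6 (C_b) + 2 (C_m).

#' Per-frame mean TAC over a set of voxel curves
#'
#' @param voxel_tacs list of [tac_curve()]s sharing one time grid.
#' @return a [tac_curve()] with the per-frame arithmetic mean.
#' @export
roi_mean_tac <- function(voxel_tacs) {
  assert_that(is.list(voxel_tacs) && length(voxel_tacs) >= 1,
              "need at least one voxel curve")
  assert_that(all(vapply(voxel_tacs, inherits, logical(1), "tac_curve")),
              "voxel_tacs must be tac_curve objects")
  t0 <- voxel_tacs[[1]]$times
  for (v in voxel_tacs)
    if (length(v$times) != length(t0) || any(abs(v$times - t0) > 1e-9))
      stop_input("voxel curves must share an identical time grid")
  m <- rowMeans(vapply(voxel_tacs, `[[`, numeric(length(t0)), "values"))
  tac_curve(t0, m, voxel_tacs[[1]]$component)
}

#' Interpolated TAC value at an arbitrary time
#'
#' Linear interpolation between the bracketing samples; exact at sample
#' points; errors outside the curve support.
#'
#' @param curve a [tac_curve()].
#' @param tau query time (minutes).
#' @return activity (kBq/mL).
#' @export
tac_value_at <- function(curve, tau) {
  assert_that(inherits(curve, "tac_curve"), "curve must be a tac_curve")
  assert_that(is_num1(tau), "tau must be a finite scalar")
  interp_lin(curve$times, curve$values, tau, what = "tau")
}

#' TAC slope between two anchor times
#'
#' `(TAC(t2) - TAC(t1)) / (t2 - t1)` with linear interpolation at the
#' anchors. With the defaults (10, 30 min) this is the 10-30 min washout
#' slope; applied to the bone-marrow free component it is the BCS biomarker,
#' negative for a declining curve.
#'
#' @param curve a [tac_curve()].
#' @param t1,t2 anchor times in minutes, `t2 > t1`, within support.
#' @return slope (kBq/mL/min).
#' @export
slope_between <- function(curve, t1 = 10, t2 = 30) {
  assert_that(is_num1(t1) && is_num1(t2) && t2 > t1, "need t2 > t1")
  (tac_value_at(curve, t2) - tac_value_at(curve, t1)) / (t2 - t1)
}

#' Trapezoidal area under the whole TAC
#'
#' @param curve a [tac_curve()] with at least two samples.
#' @return area (kBq/mL * min).
#' @export
auc_t <- function(curve) {
  assert_that(inherits(curve, "tac_curve"), "curve must be a tac_curve")
  trapz(curve$times, curve$values)
}

#' Peak-related TAC features
#'
#' `TAC_max` is the maximum sample value and `Time_TM` the earliest time
#' attaining it. `Slope_0_max = (TAC_max - TAC(first)) / (Time_TM - t_first)`
#' (0 when the peak is at the first sample); `Slope_max_60 =
#' (TAC(60) - TAC_max) / (60 - Time_TM)` (0 when `Time_TM >= 60`), both with
#' the uniform (later - earlier)/dt sign convention.
#'
#' @param curve a [tac_curve()]; must reach `slope_to` minutes for the
#'   post-peak slope.
#' @param slope_to end anchor of the post-peak slope (default 60 min).
#' @return named numeric: `TAC_max`, `Time_TM`, `Slope_0_max`, `Slope_max_60`.
#' @export
peak_features <- function(curve, slope_to = 60) {
  assert_that(inherits(curve, "tac_curve"), "curve must be a tac_curve")
  tmax_i <- which.max(curve$values)      # earliest index attaining the max
  tac_max <- curve$values[tmax_i]
  time_tm <- curve$times[tmax_i]
  s0 <- if (tmax_i == 1) 0 else
    (tac_max - curve$values[1]) / (time_tm - curve$times[1])
  if (time_tm >= slope_to) {
    s60 <- 0
  } else {
    if (curve$times[length(curve$times)] < slope_to - 1e-9)
      stop_input("curve does not reach ", slope_to,
                 " min; post-peak slope undefined")
    s60 <- (tac_value_at(curve, slope_to) - tac_max) / (slope_to - time_tm)
  }
  c(TAC_max = tac_max, Time_TM = time_tm, Slope_0_max = s0, Slope_max_60 = s60)
}

## six operators applied to one component curve
component_features <- function(curve, full = TRUE) {
  pk <- peak_features(curve)
  if (full) {
    c(Slope_10_30 = slope_between(curve, 10, 30),
      AUC_T = auc_t(curve),
      Slope_0_max = pk[["Slope_0_max"]],
      Slope_max_60 = pk[["Slope_max_60"]],
      Time_TM = pk[["Time_TM"]],
      TAC_max = pk[["TAC_max"]])
  } else {
    c(Slope_0_max = pk[["Slope_0_max"]], TAC_max = pk[["TAC_max"]])
  }
}

#' Canonical kinetic feature names (frozen contract)
#'
#' 28 names: for each ROI (`T`, `BM`), 6 features on `Cf`, 6 on `Cb`, 2 on
#' `Cm`, named `<ROI>_<comp>_<feature>` (e.g. `BM_Cf_Slope_10_30` is the BCS
#' biomarker).
#'
#' @return character vector of length 28.
#' @export
kinetic_feature_names <- function() {
  six <- c("Slope_10_30", "AUC_T", "Slope_0_max", "Slope_max_60",
           "Time_TM", "TAC_max")
  two <- c("Slope_0_max", "TAC_max")
  unlist(lapply(c("T", "BM"), function(roi)
    c(paste(roi, "Cf", six, sep = "_"),
      paste(roi, "Cb", six, sep = "_"),
      paste(roi, "Cm", two, sep = "_"))))
}

#' Assemble the 28-feature kinetic vector
#'
#' @param tumor,bone_marrow decomposed component lists (as returned by
#'   [decompose()]): fields `cb`, `cf`, `cm`, each a [tac_curve()].
#' @return named numeric vector of length 28, in [kinetic_feature_names()]
#'   order.
#' @export
extract_feature_vector <- function(tumor, bone_marrow) {
  rois <- list(T = tumor, BM = bone_marrow)
  out <- unlist(lapply(names(rois), function(nm) {
    d <- rois[[nm]]
    for (comp in c("cb", "cf", "cm"))
      if (is.null(d[[comp]]))
        stop_input("missing component '", comp, "' for ROI ", nm)
    v <- c(component_features(d$cf, TRUE),
           component_features(d$cb, TRUE),
           component_features(d$cm, FALSE))
    names(v) <- c(paste(nm, "Cf", names(v)[1:6], sep = "_"),
                  paste(nm, "Cb", names(v)[7:12], sep = "_"),
                  paste(nm, "Cm", names(v)[13:14], sep = "_"))
    v
  }))
  stopifnot(identical(names(out), kinetic_feature_names()))
  out
}

#' Conventional SUV / MTV / TLG metrics
#'
#' SUV statistics over the tumor and bone-marrow voxel arrays; metabolic
#' tumor volume `MTV = count(SUV >= threshold) * voxel_volume`; total lesion
#' glycolysis `TLG = MTV * mean SUV of the supra-threshold voxels`.
#'
#' @param tumor_suv,bm_suv numeric voxel SUV arrays (non-empty).
#' @param voxel_volume_mL voxel volume (mL, > 0).
#' @param threshold SUV threshold for MTV (default 2.5).
#' @return named numeric: `T_SUVmax`, `T_SUVmean`, `T_SUVmin`, `BM_SUVmax`,
#'   `BM_SUVmean`, `BM_SUVmin`, `MTV`, `TLG`.
#' @export
conventional_features <- function(tumor_suv, bm_suv, voxel_volume_mL,
                                  threshold = 2.5) {
  assert_that(is.numeric(tumor_suv) && length(tumor_suv) >= 1,
              "tumor ROI is empty")
  assert_that(is.numeric(bm_suv) && length(bm_suv) >= 1, "bone-marrow ROI is empty")
  assert_that(is_num1(voxel_volume_mL) && voxel_volume_mL > 0,
              "voxel_volume_mL must be > 0")
  above <- tumor_suv >= threshold
  mtv <- sum(above) * voxel_volume_mL
  tlg <- if (any(above)) mtv * mean(tumor_suv[above]) else 0
  c(T_SUVmax = max(tumor_suv), T_SUVmean = mean(tumor_suv),
    T_SUVmin = min(tumor_suv),
    BM_SUVmax = max(bm_suv), BM_SUVmean = mean(bm_suv),
    BM_SUVmin = min(bm_suv),
    MTV = mtv, TLG = tlg)
}
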