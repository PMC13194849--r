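## File dialects: TAC CSV, cohort CSV, feature CSV and JSON reports. All
## readers validate the schema strictly and name the offending column or row.

TAC_COLUMNS <- c("patient_id", "roi", "frame_start_s", "frame_end_s",
                 "activity_kbq_per_ml")
COHORT_COLUMNS <- c("patient_id", "pfs_days", "event")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_input(what, " is missing required column(s): ",
               paste(missing, collapse = ", "))
}

#' Read / write the long-format TAC CSV
#'
#' Columns: `patient_id`, `roi` (one of `tumor`, `bone_marrow`, `blood`),
#' `frame_start_s`, `frame_end_s`, `activity_kbq_per_ml`.
#'
#' @param path file path.
#' @return data.frame in the TAC dialect.
#' @export
read_tac_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, TAC_COLUMNS, "TAC CSV")
  bad <- which(!df$roi %in% c("tumor", "bone_marrow", "blood"))
  if (length(bad))
    stop_input("TAC CSV row ", bad[1] + 1, ": invalid roi '", df$roi[bad[1]], "'")
  for (col in c("frame_start_s", "frame_end_s", "activity_kbq_per_ml")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop_input("TAC CSV row ", bad[1] + 1, ": non-numeric ", col)
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(df$frame_end_s <= df$frame_start_s)
  if (length(bad))
    stop_input("TAC CSV row ", bad[1] + 1, ": frame_end_s <= frame_start_s")
  df
}

#' @rdname read_tac_csv
#' @param tac data.frame in the TAC dialect.
#' @export
write_tac_csv <- function(tac, path) {
  check_columns(tac, TAC_COLUMNS, "TAC table")
  write.csv(tac[, TAC_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the cohort CSV
#'
#' Requires `patient_id`, `pfs_days` (> 0), `event` (0/1); any further
#' columns are treated as clinical covariates.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, COHORT_COLUMNS, "cohort CSV")
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$pfs_days))) |
                 suppressWarnings(as.numeric(df$pfs_days)) <= 0)
  if (length(bad))
    stop_input("cohort CSV row ", bad[1] + 1, ": pfs_days must be positive")
  df$pfs_days <- as.numeric(df$pfs_days)
  bad <- which(!df$event %in% c(0, 1))
  if (length(bad))
    stop_input("cohort CSV row ", bad[1] + 1, ": event must be 0 or 1")
  df$event <- as.integer(df$event)
  df
}

#' @rdname read_cohort_csv
#' @param cohort data.frame with at least the required columns.
#' @export
write_cohort_csv <- function(cohort, path) {
  check_columns(cohort, COHORT_COLUMNS, "cohort table")
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the per-patient feature matrix CSV
#'
#' One row per patient: `patient_id`, the 28 kinetic features in canonical
#' order, the 8 conventional features, then any clinical covariates.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, "patient_id", "feature CSV")
  df
}

#' @rdname read_feature_csv
#' @param features data.frame with a `patient_id` column.
#' @export
write_feature_csv <- function(features, path) {
  check_columns(features, "patient_id", "feature table")
  write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a report (or any list) as pretty JSON
#' @param x a list.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Build a frame schedule from a TAC table's frames for one patient/ROI
#' @param tac TAC data.frame (one patient, one roi).
#' @return a [frame_schedule()].
#' @export
schedule_from_tac <- function(tac) {
  tac <- tac[order(tac$frame_start_s), ]
  frame_schedule(tac$frame_start_s, tac$frame_end_s)
}
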