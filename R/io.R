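#' Read a creatinine measurement extract
#'
#' Reads a hospital-extract CSV with header
#' `patient_id,measured_at,creatinine_umol_l,age_days,sex,centre`
#' (ISO-8601 date-times). Rows that cannot be used — unparseable timestamp,
#' non-positive or non-numeric creatinine, bad age, age outside the
#' eligibility window, unknown sex — are not dropped silently: they are
#' returned in a rejects table with a reason per row, and
#' `nrow(measurements) + nrow(rejects)` always equals the input row count.
#'
#' @param path CSV file path.
#' @param age_min_days,age_max_days Eligibility window in days of age
#'   (default 29 days to 18 years).
#' @return List with `measurements` (typed tibble ready for
#'   [evaluate_stream()]) and `rejects` (original fields as text plus
#'   `row` and `reason`).
#' @export
read_measurements <- function(path, age_min_days = .age_min_default,
                              age_max_days = .age_max_default) {
  abort_if(!file.exists(path), paste0("measurements file not found: ", path))
  need <- c("patient_id", "measured_at", "creatinine_umol_l", "age_days",
            "sex", "centre")
  raw <- suppressWarnings(readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE))
  missing_cols <- setdiff(need, names(raw))
  abort_if(length(missing_cols) > 0,
           paste0("malformed header; expected columns ",
                  paste(need, collapse = ", "), "; missing: ",
                  paste(missing_cols, collapse = ", ")))
  raw <- raw[need]

  ts <- suppressWarnings(readr::parse_datetime(raw$measured_at))
  attr(ts, "problems") <- NULL
  ts <- as.POSIXct(ts, tz = "UTC")
  val <- suppressWarnings(as.numeric(raw$creatinine_umol_l))
  age <- suppressWarnings(as.numeric(raw$age_days))
  sex <- tolower(raw$sex)

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) {
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- flag(is.na(raw$patient_id) | raw$patient_id == "",
                 "missing patient_id")
  reason <- flag(is.na(ts), "unparseable measured_at")
  reason <- flag(is.na(val) | val <= 0, "non-positive or non-numeric creatinine")
  reason <- flag(is.na(age), "non-numeric age_days")
  reason <- flag(!is.na(age) & (age < age_min_days | age >= age_max_days),
                 "age outside eligibility window")
  reason <- flag(is.na(sex) | !sex %in% .sex_levels, "unknown sex")
  reason <- flag(is.na(raw$centre) | raw$centre == "", "missing centre")

  ok <- is.na(reason)
  measurements <- tibble::tibble(
    patient_id = raw$patient_id[ok], measured_at = ts[ok],
    creatinine_umol_l = val[ok], age_days = age[ok],
    sex = sex[ok], centre = raw$centre[ok])
  rejects <- dplyr::bind_cols(
    tibble::tibble(row = which(!ok)),
    raw[!ok, , drop = FALSE],
    tibble::tibble(reason = reason[!ok]))
  list(measurements = measurements, rejects = rejects)
}

#' Read a recognition-audit table
#'
#' CSV with header `patient_id,recognised` plus optional management-item
#' columns; `recognised` must be `yes`, `no` or `no_information`, and item
#' columns are parsed as logicals (`yes/no`, `true/false`, `1/0`).
#'
#' @param path CSV file path.
#' @return Tibble accepted by [recognition_summary()].
#' @export
read_audit <- function(path) {
  abort_if(!file.exists(path), paste0("audit file not found: ", path))
  raw <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  abort_if(!all(c("patient_id", "recognised") %in% names(raw)),
           "malformed header; expected columns patient_id, recognised, ...")
  raw$recognised <- tolower(raw$recognised)
  items <- setdiff(names(raw), c("patient_id", "recognised"))
  for (col in items) {
    v <- tolower(raw[[col]])
    raw[[col]] <- dplyr::case_match(v, c("yes", "true", "1") ~ TRUE,
                                    c("no", "false", "0") ~ FALSE,
                                    .default = NA)
  }
  raw
}

# ISO-8601 UTC text for CSV output
iso_time <- function(t) {
  out <- format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out[is.na(t)] <- NA_character_
  out
}

write_time_csv <- function(df, path) {
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct")) df[[col]] <- iso_time(df[[col]])
  }
  readr::write_csv(df, path, na = "")
  invisible(path)
}

# plain-list view of a cohort report for JSON serialization
report_to_list <- function(report) {
  abort_if(!inherits(report, "aki_cohort_report"),
           "report must be an aki_cohort_report")
  out <- unclass(report)
  as_named <- function(v) as.list(v)
  for (f in c("stage_counts", "stage_mix_pct", "age_band_counts",
              "age_band_pct", "recognition_counts", "recognition_pct")) {
    if (!is.null(out[[f]])) out[[f]] <- as_named(out[[f]])
  }
  if (!is.null(out$per_centre)) out$per_centre <- as.data.frame(out$per_centre)
  if (!is.null(out$audit)) {
    out$audit$counts <- as.list(out$audit$counts)
    out$audit$pct <- as.list(out$audit$pct)
    if (!is.null(out$audit$management)) {
      out$audit$management <- lapply(out$audit$management, as.list)
    }
  }
  if (!is.null(out$comparisons)) {
    out$comparisons <- lapply(out$comparisons, function(cmp) {
      if (!is.null(cmp$corrected)) cmp$corrected <- unclass(cmp$corrected)
      cmp
    })
  }
  out
}

#' Write a cohort report as JSON
#'
#' Serializes deterministically: identical reports produce byte-identical
#' files. Undefined rates (`NA`) are written as JSON `null`.
#'
#' @param report An `aki_cohort_report`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null", pretty = TRUE)
  invisible(path)
}
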