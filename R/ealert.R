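#' AKI stage from a creatinine fold-rise
#'
#' Maps the ratio of a creatinine measurement to its baseline onto an AKI
#' stage: ratios below 1.5 carry no alert (stage 0); stage 1 is a rise of
#' at least 1.5-fold and below 2-fold; stage 2 at least 2-fold and below
#' 3-fold; stage 3 at least 3-fold. All thresholds are lower-inclusive,
#' upper-exclusive.
#'
#' @param ratio Numeric vector of positive fold-rises (measurement / baseline).
#' @return Integer vector with values 0 (no alert), 1, 2 or 3.
#' @examples
#' stage_from_ratio(c(1.0, 1.5, 1.999999, 2, 2.999999, 3, 8))
#' @export
stage_from_ratio <- function(ratio) {
  abort_if(!is.numeric(ratio), "ratio must be numeric")
  abort_if(anyNA(ratio) || any(ratio <= 0),
           "ratio must be positive and non-missing")
  findInterval(ratio, c(1.5, 2, 3))
}

#' Resolve the baseline creatinine for one measurement
#'
#' The baseline is the lowest creatinine value recorded for the patient in
#' the 12 months strictly before the index time `t` (window
#' `[t - 365 days, t)`). When no measurement falls in that window the
#' age-specific upper reference limit is used instead.
#'
#' @param history Data frame of the patient's other measurements with columns
#'   `measured_at` (POSIXct) and `creatinine_umol_l`. May have zero rows.
#' @param t POSIXct time of the index measurement.
#' @param age_days Patient age in days at time `t`.
#' @param sex `"any"`, `"male"` or `"female"` (used only for the reference
#'   fallback).
#' @param reference An [reference_table()].
#' @return A one-row tibble with `baseline_umol_l`, `baseline_source`
#'   (`"prior_minimum"` or `"reference_upper_limit"`), `window_start`,
#'   `window_end`, and `baseline_measured_at` (time of the earliest in-window
#'   minimum; `NA` for the reference fallback).
#' @examples
#' hist <- data.frame(
#'   measured_at = as.POSIXct("2012-08-01", tz = "UTC") - c(100, 30) * 86400,
#'   creatinine_umol_l = c(38, 45)
#' )
#' compute_baseline(hist, as.POSIXct("2012-08-01", tz = "UTC"), age_days = 400)
#' @export
compute_baseline <- function(history, t, age_days, sex = "any",
                             reference = default_reference_table()) {
  abort_if(!inherits(t, "POSIXct") || length(t) != 1 || is.na(t),
           "t must be a single POSIXct time")
  if (nrow(history) > 0) {
    abort_if(!inherits(history$measured_at, "POSIXct"),
             "history$measured_at must be POSIXct")
    abort_if(any(history$creatinine_umol_l <= 0),
             "history contains non-positive creatinine values")
  }
  window_start <- t - .window_secs
  keep <- nrow(history) > 0 &
    history$measured_at >= window_start & history$measured_at < t
  if (any(keep)) {
    vals <- history$creatinine_umol_l[keep]
    times <- history$measured_at[keep]
    m <- min(vals)
    tibble::tibble(
      baseline_umol_l = m,
      baseline_source = "prior_minimum",
      window_start = window_start, window_end = t,
      baseline_measured_at = min(times[vals == m])
    )
  } else {
    tibble::tibble(
      baseline_umol_l = upper_reference_limit(age_days, sex, reference),
      baseline_source = "reference_upper_limit",
      window_start = window_start, window_end = t,
      baseline_measured_at = as.POSIXct(NA, tz = "UTC")
    )
  }
}

#' Evaluate a single measurement against a patient history
#'
#' Resolves the baseline, computes the fold-rise and stage, and returns an
#' alert record when the stage is 1 or higher, otherwise `NULL`.
#'
#' @param value Creatinine concentration in µmol/L.
#' @inheritParams compute_baseline
#' @return A one-row tibble (`value_umol_l`, `measured_at`, baseline fields,
#'   `ratio`, `stage`) or `NULL` when no alert is raised.
#' @export
evaluate_measurement <- function(value, t, age_days, sex = "any",
                                 history = data.frame(), reference = default_reference_table()) {
  abort_if(!is.numeric(value) || length(value) != 1 || is.na(value) || value <= 0,
           "value must be a single positive number")
  base <- compute_baseline(history, t, age_days, sex, reference)
  ratio <- value / base$baseline_umol_l
  stage <- stage_from_ratio(ratio)
  if (stage < 1L) return(NULL)
  tibble::tibble(
    measured_at = t, value_umol_l = value, age_days = age_days,
    base, ratio = ratio, stage = stage
  )
}

# sliding-window minimum over one patient's time-sorted measurements.
# Returns, for each index i, the minimum value with
# times[j] in [times[i] - 365d, times[i]) and the earliest time attaining it.
# Monotonic-deque algorithm: O(n) per patient.
window_min_prior <- function(times, values) {
  n <- length(times)
  min_val <- rep(NA_real_, n)
  min_time <- rep(NA_real_, n)
  dq <- integer(n)
  head_i <- 1L; tail_i <- 0L; p <- 1L
  tt <- as.numeric(times)
  for (i in seq_len(n)) {
    t_i <- tt[i]
    ws <- t_i - .window_secs
    while (p <= n && tt[p] < t_i) {
      # drop candidates strictly larger than the newcomer; equal values keep
      # the earlier timestamp at the front, which records tie provenance
      while (tail_i >= head_i && values[dq[tail_i]] > values[p]) {
        tail_i <- tail_i - 1L
      }
      tail_i <- tail_i + 1L
      dq[tail_i] <- p
      p <- p + 1L
    }
    while (head_i <= tail_i && tt[dq[head_i]] < ws) head_i <- head_i + 1L
    if (head_i <= tail_i) {
      min_val[i] <- values[dq[head_i]]
      min_time[i] <- tt[dq[head_i]]
    }
  }
  list(value = min_val, time = .POSIXct(min_time, tz = "UTC"))
}

# slower sequential path used when alert-triggering values are excluded from
# baseline candidacy: each alert decision feeds back into later baselines
window_min_prior_masked <- function(times, values, limits) {
  n <- length(times)
  min_val <- rep(NA_real_, n)
  min_time <- rep(NA_real_, n)
  alerted <- logical(n)
  tt <- as.numeric(times)
  for (i in seq_len(n)) {
    keep <- tt >= tt[i] - .window_secs & tt < tt[i] & !alerted
    if (any(keep)) {
      m <- min(values[keep])
      min_val[i] <- m
      min_time[i] <- min(tt[keep][values[keep] == m])
      alerted[i] <- values[i] / m >= 1.5
    } else {
      alerted[i] <- values[i] / limits[i] >= 1.5
    }
  }
  list(value = min_val, time = .POSIXct(min_time, tz = "UTC"))
}

validate_measurements <- function(m, age_min_days, age_max_days) {
  abort_if(!is.data.frame(m), "measurements must be a data frame")
  need <- c("patient_id", "measured_at", "creatinine_umol_l", "age_days",
            "sex", "centre")
  missing_cols <- setdiff(need, names(m))
  abort_if(length(missing_cols) > 0,
           paste0("measurements are missing columns: ",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(m) == 0) return(invisible(TRUE))
  abort_if(!inherits(m$measured_at, "POSIXct") || anyNA(m$measured_at),
           "measured_at must be POSIXct with no missing values")
  abort_if(!is.numeric(m$creatinine_umol_l) || anyNA(m$creatinine_umol_l) ||
             any(m$creatinine_umol_l <= 0),
           "creatinine_umol_l must be positive with no missing values")
  abort_if(!is.numeric(m$age_days) || anyNA(m$age_days) ||
             any(m$age_days < age_min_days | m$age_days >= age_max_days),
           paste0("age_days must lie in [", age_min_days, ", ", age_max_days,
                  ") for every row; filter ineligible rows before evaluation"))
  abort_if(!all(m$sex %in% .sex_levels),
           "sex must be one of 'any', 'male', 'female'")
  invisible(TRUE)
}

#' Run the e-alert algorithm over a measurement stream
#'
#' Annotates every measurement with its resolved baseline, fold-rise and
#' stage, and extracts the alerts (stage >= 1). For each measurement the
#' baseline is the patient's lowest creatinine in the 365 days strictly
#' before the measurement time; measurements with no in-window prior result
#' fall back to the age-specific upper reference limit and are additionally
#' flagged when their value exceeds that limit (`above_reference`). Results
#' do not depend on the row order of the input.
#'
#' @param measurements Data frame with columns `patient_id`, `measured_at`
#'   (POSIXct), `creatinine_umol_l`, `age_days`, `sex`, `centre`.
#' @param reference An [reference_table()].
#' @param exclude_alert_baseline If `TRUE`, values that themselves raised an
#'   alert are removed from baseline candidacy for later measurements. Off by
#'   default: the algorithm as specified takes the plain 12-month minimum.
#' @param age_min_days,age_max_days Eligibility bounds; rows outside them are
#'   an error (use [read_measurements()] to divert them to a rejects table).
#' @return A list of class `aki_stream` with elements `annotated` (input rows
#'   plus `has_prior_baseline`, `above_reference`, `baseline_umol_l`,
#'   `baseline_source`, `baseline_measured_at`, `ratio`, `stage`) and
#'   `alerts` (the stage >= 1 subset).
#' @examples
#' m <- tibble::tibble(
#'   patient_id = "p1",
#'   measured_at = as.POSIXct("2012-07-01", tz = "UTC") + c(0, 10) * 86400,
#'   creatinine_umol_l = c(40, 85), age_days = c(800, 810),
#'   sex = "any", centre = "A"
#' )
#' evaluate_stream(m)$alerts
#' @export
evaluate_stream <- function(measurements, reference = default_reference_table(),
                            exclude_alert_baseline = FALSE,
                            age_min_days = .age_min_default,
                            age_max_days = .age_max_default) {
  validate_measurements(measurements, age_min_days, age_max_days)
  m <- tibble::as_tibble(measurements)
  if (nrow(m) == 0) {
    ann <- dplyr::mutate(m,
      has_prior_baseline = logical(0), above_reference = logical(0),
      baseline_umol_l = numeric(0), baseline_source = character(0),
      baseline_measured_at = as.POSIXct(character(0), tz = "UTC"),
      ratio = numeric(0), stage = integer(0))
    return(structure(list(annotated = ann, alerts = ann),
                     class = "aki_stream"))
  }
  m <- dplyr::arrange(m, .data$patient_id, .data$measured_at,
                      .data$creatinine_umol_l)
  limits <- upper_reference_limit(m$age_days, m$sex, reference)

  ann <- m |>
    dplyr::mutate(.ref_limit = limits) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ annotate_patient(.x, exclude_alert_baseline)) |>
    dplyr::ungroup()

  ann$.ref_limit <- NULL
  structure(list(annotated = ann,
                 alerts = dplyr::filter(ann, .data$stage >= 1L)),
            class = "aki_stream")
}

annotate_patient <- function(df, exclude_alert_baseline) {
  wm <- if (exclude_alert_baseline) {
    window_min_prior_masked(df$measured_at, df$creatinine_umol_l, df$.ref_limit)
  } else {
    window_min_prior(df$measured_at, df$creatinine_umol_l)
  }
  has_prior <- !is.na(wm$value)
  baseline <- ifelse(has_prior, wm$value, df$.ref_limit)
  ratio <- df$creatinine_umol_l / baseline
  df$has_prior_baseline <- has_prior
  df$above_reference <- ifelse(has_prior, NA,
                               df$creatinine_umol_l > df$.ref_limit)
  df$baseline_umol_l <- baseline
  df$baseline_source <- ifelse(has_prior, "prior_minimum",
                               "reference_upper_limit")
  df$baseline_measured_at <- wm$time
  df$ratio <- ratio
  df$stage <- stage_from_ratio(ratio)
  df
}

#' @export
print.aki_stream <- function(x, ...) {
  n <- nrow(x$annotated)
  na <- nrow(x$alerts)
  cat("AKI e-alert evaluation: ", n, " measurements, ", na, " alerts (",
      length(unique(x$alerts$patient_id)), " patients)\n", sep = "")
  if (na > 0) {
    mix <- table(factor(x$alerts$stage, levels = 1:3))
    cat("  stage mix: ", paste0("stage ", 1:3, " = ", as.integer(mix),
                                collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
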