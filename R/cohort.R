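#' Paediatric age band for an age in days
#'
#' Bands are half-open on whole years of 365 days:
#' `[0,1)`, `[1,6)`, `[6,11)`, `[11,16)`, `[16,18)` years. An age of exactly
#' 365 days therefore falls in the `1-<6y` band.
#'
#' @param age_days Numeric vector of ages in days.
#' @return Factor with levels `<1y`, `1-<6y`, `6-<11y`, `11-<16y`, `16-<18y`.
#' @export
age_band <- function(age_days) {
  abort_if(!is.numeric(age_days) || anyNA(age_days),
           "age_days must be numeric with no missing values")
  abort_if(any(age_days < 0 | age_days >= 18 * 365),
           "age_days outside the eligible range [0, 18y)")
  cut(age_days, breaks = 365 * c(0, 1, 6, 11, 16, 18),
      labels = .age_band_levels, right = FALSE)
}

.age_band_levels <- c("<1y", "1-<6y", "6-<11y", "11-<16y", "16-<18y")

#' Summarise alerts per patient
#'
#' Collapses an alert table to one row per patient: worst (maximum) stage,
#' number of alerts, and the age band and centre taken at the patient's first
#' alert, so a patient alerting across a birthday or a transfer is counted in
#' exactly one band and one centre.
#'
#' @param alerts Alert rows as produced by [evaluate_stream()] (requires
#'   `patient_id`, `measured_at`, `age_days`, `centre`, `stage`).
#' @return Tibble with columns `patient_id`, `worst_stage`, `n_alerts`,
#'   `first_alert_at`, `age_band`, `centre`.
#' @export
summarise_patients <- function(alerts) {
  abort_if(!is.data.frame(alerts), "alerts must be a data frame")
  need <- c("patient_id", "measured_at", "age_days", "centre", "stage")
  missing_cols <- setdiff(need, names(alerts))
  abort_if(length(missing_cols) > 0,
           paste0("alerts are missing columns: ",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(alerts) == 0) {
    return(tibble::tibble(
      patient_id = character(0), worst_stage = integer(0),
      n_alerts = integer(0),
      first_alert_at = as.POSIXct(character(0), tz = "UTC"),
      age_band = factor(character(0), levels = .age_band_levels),
      centre = character(0)))
  }
  abort_if(!all(alerts$stage %in% 1:3), "alert stages must be 1, 2 or 3")
  alerts |>
    dplyr::arrange(.data$patient_id, .data$measured_at) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      worst_stage = max(.data$stage),
      n_alerts = dplyr::n(),
      first_alert_at = .data$measured_at[1],
      age_band = age_band(.data$age_days[1]),
      centre = .data$centre[1],
      .groups = "drop"
    )
}

#' Cohort report from raw counts
#'
#' Computes the headline aggregates of an e-alert audit directly from counts:
#' baseline coverage, the alert rate over all measurements and restricted to
#' measurements with a prior-year baseline, the above-reference rate among
#' measurements without one, the stage mix over alerts, age-band percentages
#' over alerted patients, and (optionally) the case-note review fraction and
#' recognition split. Rates use `rate_digits` decimals; mixes and splits use
#' `mix_digits`. All percentages round half away from zero. A zero
#' denominator yields `NA` ("undefined"), never 0.
#'
#' @param n_measurements Total creatinine measurements analysed.
#' @param n_with_prior_baseline Measurements with a creatinine result in the
#'   preceding 12 months.
#' @param n_alerts Alert-bearing measurements (all among the prior-baseline
#'   group).
#' @param n_alert_patients Distinct patients with at least one alert.
#' @param n_above_reference Measurements lacking a prior baseline whose value
#'   exceeded the age reference upper limit.
#' @param stage_counts Named or ordered numeric vector of length 3: alerts at
#'   stages 1, 2, 3. Must sum to `n_alerts`.
#' @param age_band_counts Optional named vector of alerted patients per age
#'   band (names from [age_band()] levels); must sum to `n_alert_patients`.
#' @param n_reviewed,recognition_counts Optional audit arm: number of case
#'   notes reviewed and a vector `c(yes =, no =, no_information =)` summing
#'   to `n_reviewed`.
#' @param rate_digits,mix_digits Rounding digits for rates and mixes.
#' @return A list of class `aki_cohort_report`.
#' @examples
#' rep <- cohort_report_from_counts(
#'   n_measurements = 57278, n_with_prior_baseline = 43080,
#'   n_alerts = 5325, n_alert_patients = 1112, n_above_reference = 1088,
#'   stage_counts = c(3324, 843, 1158)
#' )
#' rep$alert_rate_restricted_pct  # 12.4
#' @export
cohort_report_from_counts <- function(n_measurements, n_with_prior_baseline,
                                      n_alerts, n_alert_patients,
                                      n_above_reference,
                                      stage_counts,
                                      age_band_counts = NULL,
                                      n_reviewed = NULL,
                                      recognition_counts = NULL,
                                      rate_digits = 1, mix_digits = 0) {
  counts <- c(n_measurements, n_with_prior_baseline, n_alerts,
              n_alert_patients, n_above_reference, stage_counts)
  abort_if(anyNA(counts) || any(counts < 0),
           "all counts must be non-negative and non-missing")
  abort_if(length(stage_counts) != 3, "stage_counts must have length 3")
  abort_if(sum(stage_counts) != n_alerts,
           "stage_counts must sum to n_alerts")
  n_without <- n_measurements - n_with_prior_baseline
  abort_if(n_without < 0,
           "n_with_prior_baseline exceeds n_measurements")
  abort_if(n_alerts > 0 && n_alert_patients == 0,
           "alerts imply at least one alerted patient")

  rep <- list(
    n_measurements = n_measurements,
    n_with_prior_baseline = n_with_prior_baseline,
    n_without_prior_baseline = n_without,
    n_alerts = n_alerts,
    n_alert_patients = n_alert_patients,
    n_above_reference = n_above_reference,
    baseline_coverage_pct = pct(n_with_prior_baseline, n_measurements,
                                rate_digits),
    no_baseline_pct = pct(n_without, n_measurements, rate_digits),
    alert_rate_all_pct = pct(n_alerts, n_measurements, rate_digits),
    alert_rate_restricted_pct = pct(n_alerts, n_with_prior_baseline,
                                    rate_digits),
    above_reference_rate_pct = pct(n_above_reference, n_without, rate_digits),
    stage_counts = stats::setNames(as.numeric(stage_counts),
                                   paste0("stage", 1:3)),
    stage_mix_pct = stats::setNames(pct(as.numeric(stage_counts), n_alerts,
                                        mix_digits),
                                    paste0("stage", 1:3))
  )
  if (!is.null(age_band_counts)) {
    abort_if(is.null(names(age_band_counts)) ||
               !all(names(age_band_counts) %in% .age_band_levels),
             "age_band_counts must be named with age band levels")
    abort_if(sum(age_band_counts) != n_alert_patients,
             "age_band_counts must sum to n_alert_patients")
    rep$age_band_counts <- age_band_counts
    rep$age_band_pct <- stats::setNames(
      pct(as.numeric(age_band_counts), n_alert_patients, mix_digits),
      names(age_band_counts))
  }
  if (!is.null(n_reviewed)) {
    rep$n_reviewed <- n_reviewed
    rep$review_fraction_pct <- pct(n_reviewed, n_alert_patients, rate_digits)
  }
  if (!is.null(recognition_counts)) {
    abort_if(!all(c("yes", "no", "no_information") %in%
                    names(recognition_counts)),
             "recognition_counts needs yes, no and no_information entries")
    den <- n_reviewed %||% sum(recognition_counts)
    rep$recognition_counts <- recognition_counts
    rep$recognition_pct <- stats::setNames(
      pct(as.numeric(recognition_counts[c("yes", "no", "no_information")]),
          den, mix_digits),
      c("recognised", "not_recognised", "no_information"))
  }
  structure(rep, class = "aki_cohort_report")
}

#' Build the cohort report from an evaluated stream
#'
#' Aggregates the output of [evaluate_stream()] into the headline report:
#' counts and rates at the measurement level, stage mix over alerts, age-band
#' and per-centre distributions over alerted patients, and (when margins
#' permit) the comparison statistics — a chi-squared test of the alert rate
#' among measurements with a prior baseline against the above-reference rate
#' among those without, and an r x c chi-squared test of alert-rate
#' heterogeneity across centres.
#'
#' @param stream An `aki_stream` from [evaluate_stream()].
#' @param summaries Optional patient summaries; defaults to
#'   [summarise_patients()] on the stream's alerts.
#' @param audit Optional audit table (see [recognition_summary()]).
#' @param comparisons If `TRUE`, embed the comparison tests.
#' @inheritParams cohort_report_from_counts
#' @return A list of class `aki_cohort_report`; in addition to the count
#'   fields it carries `per_centre` (patient counts and stage mixes) and,
#'   when requested, `comparisons` and `audit`.
#' @export
build_report <- function(stream, summaries = NULL, audit = NULL,
                         comparisons = TRUE, rate_digits = 1, mix_digits = 0) {
  abort_if(!inherits(stream, "aki_stream"),
           "stream must come from evaluate_stream()")
  ann <- stream$annotated
  alerts <- stream$alerts
  summaries <- summaries %||% summarise_patients(alerts)

  stage_counts <- as.numeric(table(factor(alerts$stage, levels = 1:3)))
  band_tab <- table(summaries$age_band)
  age_band_counts <- if (nrow(summaries) > 0) {
    stats::setNames(as.numeric(band_tab), names(band_tab))
  } else NULL

  rep <- cohort_report_from_counts(
    n_measurements = nrow(ann),
    n_with_prior_baseline = sum(ann$has_prior_baseline),
    n_alerts = nrow(alerts),
    n_alert_patients = nrow(summaries),
    n_above_reference = sum(ann$above_reference, na.rm = TRUE),
    stage_counts = stage_counts,
    age_band_counts = age_band_counts,
    rate_digits = rate_digits, mix_digits = mix_digits
  )

  if (nrow(summaries) > 0) {
    rep$per_centre <- summaries |>
      dplyr::count(.data$centre, .data$worst_stage) |>
      tidyr::pivot_wider(names_from = "worst_stage", values_from = "n",
                         names_prefix = "stage", values_fill = 0) |>
      dplyr::mutate(n_patients = rowSums(dplyr::pick(
        dplyr::starts_with("stage")))) |>
      dplyr::arrange(.data$centre)
  }

  if (!is.null(audit)) {
    rep$n_reviewed <- nrow(audit)
    rep$review_fraction_pct <- pct(nrow(audit), rep$n_alert_patients,
                                   rate_digits)
    rep$audit <- recognition_summary(audit, mix_digits = mix_digits)
  }

  if (comparisons) {
    rep$comparisons <- list()
    # alerted vs not, among measurements with a prior baseline, against
    # above-reference vs not, among measurements without one
    t22 <- rbind(
      with_baseline = c(events = rep$n_alerts,
                        non_events = rep$n_with_prior_baseline - rep$n_alerts),
      without_baseline = c(events = rep$n_above_reference,
                           non_events = rep$n_without_prior_baseline -
                             rep$n_above_reference))
    rep$comparisons$alert_vs_reference <- tryCatch(
      c(chi_squared_test(t22),
        list(corrected = chi_squared_test(t22, correct = TRUE))),
      error = function(e) NULL)
    # alert-rate heterogeneity across centres, restricted to measurements
    # with a prior baseline
    restricted <- ann[ann$has_prior_baseline, , drop = FALSE]
    if (nrow(restricted) > 0 && length(unique(restricted$centre)) >= 2) {
      het <- table(restricted$centre, restricted$stage >= 1L)
      rep$comparisons$centre_heterogeneity <- tryCatch(
        chi_squared_test(unclass(as.matrix(het))),
        error = function(e) NULL)
    }
  }
  rep
}

#' Summarise a recognition audit
#'
#' The audit table has one row per reviewed patient with a `recognised`
#' column taking exactly one of `yes` (AKI identified with a documented
#' management plan), `no`, or `no_information`; any further logical columns
#' are treated as management items (e.g. daily weights, fluid balance) and
#' summarised within the recognised and not-recognised groups.
#'
#' @param audit Data frame with `patient_id` and `recognised`, plus optional
#'   logical management-item columns.
#' @param mix_digits Rounding digits for the percentages.
#' @return List with `n`, `counts`, `pct` (the three-way split over all
#'   audited patients) and `management` (per-item percentages within the
#'   recognised and not-recognised groups).
#' @examples
#' audit <- data.frame(
#'   patient_id = sprintf("p%03d", 1:123),
#'   recognised = rep(c("yes", "no", "no_information"), c(32, 87, 4))
#' )
#' recognition_summary(audit)$pct
#' @export
recognition_summary <- function(audit, mix_digits = 0) {
  abort_if(!is.data.frame(audit) || nrow(audit) == 0,
           "audit must be a non-empty data frame")
  abort_if(!all(c("patient_id", "recognised") %in% names(audit)),
           "audit needs patient_id and recognised columns")
  lev <- c("yes", "no", "no_information")
  bad <- !audit$recognised %in% lev
  abort_if(any(bad),
           paste0("unknown recognised values: ",
                  paste(unique(audit$recognised[bad]), collapse = ", ")))
  counts <- table(factor(audit$recognised, levels = lev))
  out <- list(
    n = nrow(audit),
    counts = stats::setNames(as.numeric(counts), lev),
    pct = stats::setNames(pct(as.numeric(counts), nrow(audit), mix_digits),
                          c("recognised", "not_recognised", "no_information"))
  )
  items <- names(audit)[vapply(audit, is.logical, logical(1))]
  if (length(items) > 0) {
    grp <- function(which) {
      sub <- audit[audit$recognised == which, items, drop = FALSE]
      stats::setNames(
        vapply(items, function(i) pct(sum(sub[[i]], na.rm = TRUE), nrow(sub),
                                      mix_digits), numeric(1)),
        items)
    }
    out$management <- list(recognised = grp("yes"), not_recognised = grp("no"))
  }
  out
}

#' @export
print.aki_cohort_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "undefined", paste0(v, "%"))
  cat("AKI e-alert cohort report\n")
  cat("  measurements:            ", x$n_measurements, "\n", sep = "")
  cat("  with prior baseline:     ", x$n_with_prior_baseline, " (",
      fmt(x$baseline_coverage_pct), ")\n", sep = "")
  cat("  without prior baseline:  ", x$n_without_prior_baseline, " (",
      fmt(x$no_baseline_pct), ")\n", sep = "")
  cat("  alerts:                  ", x$n_alerts, " in ", x$n_alert_patients,
      " patients\n", sep = "")
  cat("  alert rate (all):        ", fmt(x$alert_rate_all_pct), "\n", sep = "")
  cat("  alert rate (restricted): ", fmt(x$alert_rate_restricted_pct),
      "\n", sep = "")
  cat("  above reference (no baseline): ", x$n_above_reference, " (",
      fmt(x$above_reference_rate_pct), ")\n", sep = "")
  cat("  stage mix (1/2/3):       ",
      paste(fmt(x$stage_mix_pct), collapse = " / "), "\n", sep = "")
  if (!is.null(x$age_band_pct)) {
    cat("  age bands: ",
        paste(names(x$age_band_pct), fmt(x$age_band_pct), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$review_fraction_pct)) {
    cat("  case notes reviewed:     ", x$n_reviewed, " (",
        fmt(x$review_fraction_pct), ")\n", sep = "")
  }
  if (!is.null(x$audit)) {
    cat("  recognition (yes/no/no info): ",
        paste(fmt(x$audit$pct), collapse = " / "), "\n", sep = "")
  }
  if (!is.null(x$comparisons$alert_vs_reference)) {
    cat("  alert vs above-reference rate: chi-sq = ",
        signif(x$comparisons$alert_vs_reference$statistic, 4), ", p = ",
        format.pval(x$comparisons$alert_vs_reference$p_value, digits = 3),
        "\n", sep = "")
  }
  invisible(x)
}
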