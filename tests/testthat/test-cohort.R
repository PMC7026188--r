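test_that("age bands are half-open on 365-day years", {
  expect_equal(as.character(age_band(c(0, 364, 365, 2189, 2190, 5839, 5840,
                                       6569))),
               c("<1y", "<1y", "1-<6y", "1-<6y", "6-<11y", "11-<16y",
                 "16-<18y", "16-<18y"))
  expect_error(age_band(6570), "eligible")
})

test_that("patient summaries take the worst stage and first-alert band", {
  alerts <- tibble::tibble(
    patient_id = "p1",
    measured_at = T0 + c(3, 1, 2) * DAY,
    age_days = c(370, 364, 366),  # first alert (day 1) is under 1y
    centre = "A", stage = c(1L, 3L, 2L))
  s <- summarise_patients(alerts)
  expect_equal(s$worst_stage, 3L)
  expect_equal(s$n_alerts, 3L)
  expect_equal(as.character(s$age_band), "<1y")

  # an alert at exactly 365 days falls in the 1-<6y band
  s2 <- summarise_patients(tibble::tibble(
    patient_id = "q", measured_at = T0, age_days = 365, centre = "B",
    stage = 2L))
  expect_equal(as.character(s2$age_band), "1-<6y")
})

test_that("per-patient maxima match a brute-force group-by on random alert sets", {
  set.seed(9)
  for (k in 1:20) {
    n <- sample(1:60, 1)
    alerts <- tibble::tibble(
      patient_id = sample(sprintf("p%02d", 1:12), n, replace = TRUE),
      measured_at = T0 + runif(n, 0, 180) * DAY,
      age_days = sample(29:6569, n, replace = TRUE),
      centre = sample(c("A", "B"), n, replace = TRUE),
      stage = sample(1:3, n, replace = TRUE))
    s <- summarise_patients(alerts)
    want <- tapply(alerts$stage, alerts$patient_id, max)
    expect_equal(s$worst_stage, as.integer(want[s$patient_id]),
                 ignore_attr = TRUE)
    expect_equal(sum(s$n_alerts), n)
    expect_true(all(s$n_alerts >= 1))
  }
})

test_that("count-based report reproduces published-style arithmetic", {
  rep <- cohort_report_from_counts(
    n_measurements = 57278, n_with_prior_baseline = 43080,
    n_alerts = 5325, n_alert_patients = 1112, n_above_reference = 1088,
    stage_counts = c(3324, 843, 1158),
    age_band_counts = c("<1y" = 222, "1-<6y" = 432, "6-<11y" = 192,
                        "11-<16y" = 207, "16-<18y" = 59),
    n_reviewed = 123,
    recognition_counts = c(yes = 32, no = 87, no_information = 4))
  expect_equal(rep$alert_rate_restricted_pct, 12.4)
  expect_equal(rep$above_reference_rate_pct, 7.7)
  expect_equal(rep$baseline_coverage_pct, 75.2)
  expect_equal(rep$no_baseline_pct, 24.8)
  expect_equal(unname(rep$stage_mix_pct), c(62, 16, 22))
  expect_equal(rep$review_fraction_pct, 11.1)
  expect_equal(unname(rep$recognition_pct), c(26, 71, 3))
  expect_equal(unname(rep$age_band_pct["1-<6y"]), 39)
  # the alerts/all-measurements rate follows from the counts themselves
  expect_equal(rep$alert_rate_all_pct, 9.3)
})

test_that("zero denominators yield undefined rates, never zero", {
  rep <- cohort_report_from_counts(
    n_measurements = 0, n_with_prior_baseline = 0, n_alerts = 0,
    n_alert_patients = 0, n_above_reference = 0, stage_counts = c(0, 0, 0))
  expect_true(is.na(rep$alert_rate_all_pct))
  expect_true(is.na(rep$alert_rate_restricted_pct))
  expect_true(is.na(rep$above_reference_rate_pct))
  expect_error(cohort_report_from_counts(
    n_measurements = 10, n_with_prior_baseline = 20, n_alerts = 0,
    n_alert_patients = 0, n_above_reference = 0, stage_counts = c(0, 0, 0)),
    "exceeds")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5, -2.5)),
               c(1, 2, 3, -1, -3))
  expect_equal(round_half_up(c(12.35, 7.65), 1), c(12.4, 7.7))
  expect_equal(round_half_up(26.5), 27)
})

test_that("recognition summary counts match direct counting and sum to 100", {
  audit <- data.frame(
    patient_id = sprintf("a%03d", 1:123),
    recognised = rep(c("yes", "no", "no_information"), c(32, 87, 4)))
  rs <- recognition_summary(audit)
  expect_equal(unname(rs$pct), c(26, 71, 3))
  expect_equal(sum(rs$pct), 100)
  expect_equal(unname(rs$counts), c(32, 87, 4))

  all_yes <- data.frame(patient_id = "x", recognised = "yes")
  expect_equal(unname(recognition_summary(all_yes)$pct), c(100, 0, 0))
  expect_error(recognition_summary(
    data.frame(patient_id = "x", recognised = "maybe")), "unknown")

  set.seed(4)
  for (k in 1:10) {
    n <- sample(5:200, 1)
    rec <- sample(c("yes", "no", "no_information"), n, replace = TRUE)
    aud <- data.frame(patient_id = seq_len(n), recognised = rec,
                      weighed = sample(c(TRUE, FALSE), n, replace = TRUE))
    rs <- recognition_summary(aud, mix_digits = 4)
    expect_equal(unname(rs$counts),
                 unname(c(sum(rec == "yes"), sum(rec == "no"),
                          sum(rec == "no_information"))))
    expect_equal(sum(rs$pct), 100, tolerance = 1e-3)
    if (any(rec == "yes")) {
      expect_equal(unname(rs$management$recognised["weighed"]),
                   round_half_up(100 * mean(aud$weighed[rec == "yes"]), 4))
    }
  }
})

test_that("stream-based report is consistent and order-invariant", {
  m <- random_cohort(n_patients = 60, seed = 505)
  s <- evaluate_stream(m)
  rep <- build_report(s)
  expect_equal(rep$n_with_prior_baseline + rep$n_without_prior_baseline,
               rep$n_measurements)
  expect_equal(rep$n_measurements, nrow(m))
  expect_equal(sum(rep$stage_counts), rep$n_alerts)
  if (rep$n_alerts > 0) {
    expect_lte(abs(sum(rep$stage_mix_pct) - 100), 1)
    expect_equal(sum(rep$age_band_counts), rep$n_alert_patients)
    expect_equal(sum(rep$per_centre$n_patients), rep$n_alert_patients)
  }
  rep2 <- build_report(evaluate_stream(m[sample(nrow(m)), ]))
  expect_equal(report_json_text(rep), report_json_text(rep2))
})
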