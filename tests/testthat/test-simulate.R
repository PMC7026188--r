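test_that("invalid configurations are refused before generation", {
  expect_error(simulation_config(n_patients = 0), "at least 1")
  expect_error(simulation_config(episode_prevalence = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(stage_mix = c(0.5, 0.5)), "stage_mix")
  expect_error(simulation_config(noise_cv = -0.1), "non-negative")
  expect_error(simulation_config(baseline_fraction_of_limit = c(0.8, 0.4)),
               "increasing")
  expect_error(simulate_cohort(list(n_patients = 5)), "simulation_config")
})

test_that("identical seeds reproduce identical cohorts", {
  cfg <- simulation_config(n_patients = 40, seed = 12)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$truth$patients, s2$truth$patients)
  s3 <- simulate_cohort(simulation_config(n_patients = 40, seed = 13))
  expect_false(identical(s1$measurements, s3$measurements))
})

test_that("a null cohort yields no alerts and perfect specificity", {
  cfg <- simulation_config(n_patients = 60, episode_prevalence = 0,
                           noise_cv = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  # every measurement sits exactly at the patient's true baseline
  base <- setNames(sim$truth$patients$baseline_true_umol_l,
                   sim$truth$patients$patient_id)
  expect_equal(sim$measurements$creatinine_umol_l,
               unname(base[sim$measurements$patient_id]))
  st <- evaluate_stream(sim$measurements)
  expect_equal(nrow(st$alerts), 0)
  card <- scorecard(st, sim)
  expect_equal(card$specificity, 1)
  expect_equal(card$n_false_positive_patients, 0)
})

test_that("a designed stage-3 episode with lookback is always caught", {
  cfg <- simulation_config(n_patients = 1, episode_prevalence = 1,
                           stage_mix = c(0, 0, 1), lookback_coverage = 1,
                           noise_cv = 0, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_true(sim$truth$patients$episode)
  expect_true(sim$truth$patients$has_lookback)
  st <- evaluate_stream(sim$measurements)
  expect_true(any(st$alerts$stage == 3L))
})

test_that("noise-free full-lookback cohorts assign every episode its target stage", {
  cfg <- simulation_config(n_patients = 150, episode_prevalence = 0.3,
                           lookback_coverage = 1, noise_cv = 0, seed = 8)
  sim <- simulate_cohort(cfg)
  card <- scorecard(evaluate_stream(sim$measurements), sim)
  expect_equal(card$sensitivity, 1)
  expect_equal(card$n_detected, card$n_episode)
  # confusion strictly diagonal
  expect_equal(sum(diag(card$confusion)), sum(card$confusion))
  expect_equal(sum(card$confusion), card$n_episode)
})

test_that("raising episode prevalence never loses alerted patients", {
  n_alerted <- function(prev) {
    cfg <- simulation_config(n_patients = 80, episode_prevalence = prev,
                             seed = 44)
    sim <- simulate_cohort(cfg)
    length(unique(evaluate_stream(sim$measurements)$alerts$patient_id))
  }
  counts <- vapply(c(0, 0.1, 0.3, 0.6, 1), n_alerted, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("patients without lookback exercise the reference fallback", {
  cfg <- simulation_config(n_patients = 120, lookback_coverage = 0,
                           episode_prevalence = 0.4, seed = 19)
  sim <- simulate_cohort(cfg)
  st <- evaluate_stream(sim$measurements)
  first <- st$annotated |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$measured_at, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  expect_true(all(!first$has_prior_baseline))
  expect_equal(first$baseline_source,
               rep("reference_upper_limit", nrow(first)))
  # elevated first values are flagged as above the reference limit
  expect_true(any(first$above_reference))
})

test_that("scorecard refuses alerts from unknown patients", {
  sim <- simulate_cohort(simulation_config(n_patients = 5, seed = 3))
  fake <- tibble::tibble(patient_id = "ghost", measured_at = T0,
                         stage = 2L)
  expect_error(scorecard(fake, sim), "absent")
})

test_that("latent stream equals the noisy stream when noise is off", {
  cfg <- simulation_config(n_patients = 40, noise_cv = 0, seed = 23)
  sim <- simulate_cohort(cfg)
  expect_equal(latent_stream(sim)$annotated$ratio,
               evaluate_stream(sim$measurements)$annotated$ratio)
})
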