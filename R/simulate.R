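#' Configuration for the synthetic cohort generator
#'
#' Validates and fills the parameters of [simulate_cohort()]. Defaults
#' emulate a six-month hospital laboratory extract: a July-December 2012
#' study window, three quarters of patients carrying prior-year creatinine
#' results, a Poisson number of in-window measurements per patient, injected
#' AKI episodes in a tenth of patients with a 62/16/22 stage-1/2/3 target
#' mix, patient baselines drawn uniformly at 40-80% of the age reference
#' upper limit, 5% multiplicative lognormal measurement noise, and an age
#' distribution weighted towards the under-6s. Centre sizes follow the
#' shares of a six-centre network dominated by three tertiary hospitals.
#'
#' @param n_patients Number of patients (>= 1).
#' @param study_start,study_end POSIXct bounds of the study window.
#' @param lookback_coverage Probability a patient carries pre-window
#'   measurements (drawn within the 180 days before the window so that any
#'   in-window measurement sees them inside its 365-day lookback).
#' @param measurement_rate Expected in-window measurements per patient
#'   (Poisson).
#' @param episode_prevalence Probability a patient has one injected AKI
#'   episode.
#' @param stage_mix Probabilities over target stages 1-3; must sum to 1.
#' @param baseline_fraction_of_limit Length-2 range: patient baseline as a
#'   uniform fraction of the age reference upper limit.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 disables noise exactly).
#' @param age_distribution Weights over the five age bands
#'   (`<1y`, `1-<6y`, `6-<11y`, `11-<16y`, `16-<18y`).
#' @param centre_weights Weights over centres; length sets the number of
#'   centres.
#' @param seed Integer seed; identical configs reproduce identical cohorts.
#' @return A validated list of class `aki_sim_config`.
#' @export
simulation_config <- function(n_patients = 500,
                              study_start = as.POSIXct("2012-07-01 00:00:00",
                                                       tz = "UTC"),
                              study_end = as.POSIXct("2012-12-31 23:59:00",
                                                     tz = "UTC"),
                              lookback_coverage = 0.75,
                              measurement_rate = 3,
                              episode_prevalence = 0.1,
                              stage_mix = c(0.62, 0.16, 0.22),
                              baseline_fraction_of_limit = c(0.4, 0.8),
                              noise_cv = 0.05,
                              age_distribution = c(0.20, 0.39, 0.17, 0.19,
                                                   0.05),
                              centre_weights = c(24.5, 3.1, 1.7, 13.8, 21.1,
                                                 35.8),
                              seed = 1L) {
  abort_if(!is.numeric(n_patients) || n_patients < 1,
           "n_patients must be at least 1")
  abort_if(!inherits(study_start, "POSIXct") || !inherits(study_end, "POSIXct")
           || study_end <= study_start,
           "study window must be an ordered pair of POSIXct times")
  probs <- c(lookback_coverage, episode_prevalence)
  abort_if(any(probs < 0 | probs > 1),
           "lookback_coverage and episode_prevalence must lie in [0, 1]")
  abort_if(length(stage_mix) != 3 || any(stage_mix < 0) ||
             abs(sum(stage_mix) - 1) > 1e-8,
           "stage_mix must be 3 non-negative probabilities summing to 1")
  abort_if(length(baseline_fraction_of_limit) != 2 ||
             any(baseline_fraction_of_limit <= 0) ||
             any(baseline_fraction_of_limit >= 1) ||
             diff(baseline_fraction_of_limit) < 0,
           "baseline_fraction_of_limit must be an increasing range within (0, 1)")
  abort_if(noise_cv < 0, "noise_cv must be non-negative")
  abort_if(measurement_rate < 0, "measurement_rate must be non-negative")
  abort_if(length(age_distribution) != 5 || any(age_distribution < 0) ||
             sum(age_distribution) <= 0,
           "age_distribution must be 5 non-negative weights")
  abort_if(any(centre_weights < 0) || sum(centre_weights) <= 0 ||
             length(centre_weights) < 1,
           "centre_weights must be non-negative with positive sum")
  abort_if(!is.numeric(seed) || length(seed) != 1 || is.na(seed),
           "seed must be a single integer")
  structure(list(
    n_patients = as.integer(n_patients), study_start = study_start,
    study_end = study_end, lookback_coverage = lookback_coverage,
    measurement_rate = measurement_rate,
    episode_prevalence = episode_prevalence,
    stage_mix = stage_mix / sum(stage_mix),
    baseline_fraction_of_limit = baseline_fraction_of_limit,
    noise_cv = noise_cv,
    age_distribution = age_distribution / sum(age_distribution),
    centre_weights = centre_weights / sum(centre_weights),
    seed = as.integer(seed)
  ), class = "aki_sim_config")
}

# age ranges (days at study start) drawn per band; the youngest bound is 60
# days so every patient can carry prior-year history while staying within
# the 29-day eligibility floor, and the oldest leaves room for the study
# window below the 18-year ceiling
.band_age_lo <- c(60, 365, 6 * 365, 11 * 365, 16 * 365)
.band_age_hi <- c(365, 6 * 365, 11 * 365, 16 * 365, 18 * 365 - 185)

# ratio intervals the injected episode factor is drawn from, per target stage
.stage_factor_lo <- c(1.5, 2, 3)
.stage_factor_hi <- c(2, 3, 6)

#' Simulate a paediatric creatinine cohort with known ground truth
#'
#' Generates per-patient creatinine series: a true baseline at a fraction of
#' the age reference upper limit, optional pre-window measurements (the
#' lookback the staging algorithm needs), Poisson-timed in-window
#' measurements, an optional rectangular AKI episode during which latent
#' values are multiplied by a factor drawn inside the target stage's ratio
#' interval (stage 1: \[1.5, 2), stage 2: \[2, 3), stage 3: \[3, 6\]), and
#' multiplicative lognormal noise. An episode always carries at least one
#' in-window measurement inside its interval. Each patient's draws come from
#' a seed derived from `seed` and the patient index, so raising
#' `episode_prevalence` with everything else fixed only switches episodes on
#' without perturbing other patients.
#'
#' @param config An [simulation_config()].
#' @param reference An [reference_table()] supplying the age limits.
#' @return A list of class `aki_simulation` with `measurements` (the CSV
#'   dialect consumed by [evaluate_stream()]), `truth` (per-patient flags and
#'   per-measurement latent values) and `config`.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_patients = 20, seed = 7))
#' nrow(sim$measurements)
#' @export
simulate_cohort <- function(config, reference = default_reference_table()) {
  abort_if(!inherits(config, "aki_sim_config"),
           "config must come from simulation_config()")
  window_days <- as.numeric(difftime(config$study_end, config$study_start,
                                     units = "days"))
  sigma <- sqrt(log(1 + config$noise_cv^2))
  frac <- config$baseline_fraction_of_limit
  n_centres <- length(config$centre_weights)

  pat_rows <- vector("list", config$n_patients)
  meas_rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    set.seed(config$seed + i)
    pid <- sprintf("P%05d", i)
    band <- sample.int(5, 1, prob = config$age_distribution)
    age0 <- floor(stats::runif(1, .band_age_lo[band], .band_age_hi[band]))
    sex <- sample(c("male", "female"), 1)
    centre <- paste0("C", sample.int(n_centres, 1,
                                     prob = config$centre_weights))
    baseline_true <- stats::runif(1, frac[1], frac[2]) *
      upper_reference_limit(age0, sex, reference)

    u_look <- stats::runif(1)
    pre_span <- min(180, age0 - .age_min_default)
    has_lookback <- u_look < config$lookback_coverage && pre_span >= 1
    n_pre <- 1L + stats::rpois(1, 1)
    pre_off <- stats::runif(n_pre, -pre_span, 0)
    n_meas <- stats::rpois(1, config$measurement_rate)
    meas_off <- stats::runif(n_meas, 0, window_days)

    u_ep <- stats::runif(1)
    episode <- u_ep < config$episode_prevalence
    ep_dur <- stats::runif(1, 3, 10)
    ep_start_off <- stats::runif(1, 0, window_days - ep_dur)
    stage_target <- findInterval(stats::runif(1),
                                 cumsum(config$stage_mix)) + 1L
    stage_target <- min(stage_target, 3L)
    factor <- stats::runif(1, .stage_factor_lo[stage_target],
                           .stage_factor_hi[stage_target])
    z <- stats::rnorm(n_pre + n_meas + 1L, 0, 1)

    off <- c(if (has_lookback) pre_off, meas_off)
    z_use <- c(if (has_lookback) z[seq_len(n_pre)],
               z[n_pre + seq_len(n_meas)])
    in_ep <- episode & off >= ep_start_off & off < ep_start_off + ep_dur &
      off >= 0
    if (episode && !any(in_ep)) {
      off <- c(off, ep_start_off + ep_dur / 2)
      z_use <- c(z_use, z[n_pre + n_meas + 1L])
      in_ep <- c(in_ep, TRUE)
    }
    latent <- baseline_true * ifelse(in_ep, factor, 1)
    value <- latent * exp(sigma * z_use - sigma^2 / 2)

    pat_rows[[i]] <- tibble::tibble(
      patient_id = pid, age_days_at_start = age0, sex = sex, centre = centre,
      baseline_true_umol_l = baseline_true, has_lookback = has_lookback,
      episode = episode,
      episode_stage = if (episode) stage_target else NA_integer_,
      episode_start = if (episode) config$study_start + ep_start_off * 86400
        else as.POSIXct(NA, tz = "UTC"),
      episode_end = if (episode)
        config$study_start + (ep_start_off + ep_dur) * 86400
        else as.POSIXct(NA, tz = "UTC"))
    if (length(off) > 0) {
      meas_rows[[i]] <- tibble::tibble(
        patient_id = pid,
        measured_at = config$study_start + off * 86400,
        creatinine_umol_l = value,
        age_days = floor(age0 + off),
        sex = sex, centre = centre,
        latent_umol_l = latent, in_episode = in_ep)
    }
  }

  patients <- dplyr::bind_rows(pat_rows)
  meas <- dplyr::bind_rows(meas_rows)
  if (nrow(meas) > 0) {
    meas <- dplyr::arrange(meas, .data$patient_id, .data$measured_at)
  } else {
    meas <- tibble::tibble(
      patient_id = character(0),
      measured_at = as.POSIXct(character(0), tz = "UTC"),
      creatinine_umol_l = numeric(0), age_days = numeric(0),
      sex = character(0), centre = character(0),
      latent_umol_l = numeric(0), in_episode = logical(0))
  }
  cols <- c("patient_id", "measured_at", "creatinine_umol_l", "age_days",
            "sex", "centre")
  structure(list(
    measurements = meas[intersect(cols, names(meas))],
    truth = list(patients = patients,
                 measurements = meas[intersect(
                   c("patient_id", "measured_at", "latent_umol_l",
                     "in_episode"), names(meas))]),
    config = config
  ), class = "aki_simulation")
}

#' Evaluate the latent, noise-free series of a simulation
#'
#' Runs the staging algorithm on the simulation's latent values (the series
#' before measurement noise). This is the designed-detectability oracle: it
#' tells which episodes the algorithm can find when measurement noise is
#' absent, against which noisy-pipeline detection rates are compared.
#'
#' @param sim An `aki_simulation` from [simulate_cohort()].
#' @param reference The reference table used for the fallback path.
#' @return An `aki_stream` over the latent series.
#' @export
latent_stream <- function(sim, reference = default_reference_table()) {
  abort_if(!inherits(sim, "aki_simulation"),
           "sim must come from simulate_cohort()")
  m <- sim$measurements
  m$creatinine_umol_l <- sim$truth$measurements$latent_umol_l
  evaluate_stream(m, reference)
}

#' Score pipeline alerts against simulation ground truth
#'
#' Patient-level episode detection: an episode patient counts as detected
#' when at least one alert falls inside the episode interval; a non-episode
#' patient counts towards specificity when they have no alert at all. For
#' detected episodes the worst in-episode alert stage is tabulated against
#' the episode's target stage.
#'
#' @param stream An `aki_stream` produced from the simulated measurements
#'   (or its `alerts` element).
#' @param sim The `aki_simulation` the measurements came from.
#' @return List of class `aki_scorecard`: `sensitivity`, `specificity`
#'   (each `NA` when its group is empty), `n_episode`, `n_detected`,
#'   `n_false_positive_patients`, and `confusion` (3 x 3, target stage in
#'   rows, detected stage in columns).
#' @export
scorecard <- function(stream, sim) {
  abort_if(!inherits(sim, "aki_simulation"),
           "sim must come from simulate_cohort()")
  alerts <- if (inherits(stream, "aki_stream")) stream$alerts else stream
  abort_if(!is.data.frame(alerts), "stream must be an aki_stream or alerts")
  patients <- sim$truth$patients
  extra <- setdiff(unique(alerts$patient_id), patients$patient_id)
  abort_if(length(extra) > 0,
           paste0("alerts reference patients absent from the simulation: ",
                  paste(utils::head(extra, 5), collapse = ", ")))

  ep <- patients[patients$episode, , drop = FALSE]
  detected <- logical(nrow(ep))
  stage_det <- rep(NA_integer_, nrow(ep))
  if (nrow(ep) > 0 && nrow(alerts) > 0) {
    for (k in seq_len(nrow(ep))) {
      a <- alerts[alerts$patient_id == ep$patient_id[k] &
                    alerts$measured_at >= ep$episode_start[k] &
                    alerts$measured_at <= ep$episode_end[k], , drop = FALSE]
      detected[k] <- nrow(a) > 0
      if (detected[k]) stage_det[k] <- max(a$stage)
    }
  }
  non_ep_ids <- patients$patient_id[!patients$episode]
  fp <- intersect(unique(alerts$patient_id), non_ep_ids)

  confusion <- table(
    target = factor(ep$episode_stage[detected], levels = 1:3),
    detected = factor(stage_det[detected], levels = 1:3))
  structure(list(
    n_episode = nrow(ep),
    n_detected = sum(detected),
    sensitivity = if (nrow(ep) > 0) mean(detected) else NA_real_,
    n_non_episode = length(non_ep_ids),
    n_false_positive_patients = length(fp),
    specificity = if (length(non_ep_ids) > 0)
      1 - length(fp) / length(non_ep_ids) else NA_real_,
    confusion = unclass(confusion)
  ), class = "aki_scorecard")
}

#' @export
print.aki_scorecard <- function(x, ...) {
  cat("Episode detection scorecard\n")
  cat("  episodes: ", x$n_episode, ", detected: ", x$n_detected,
      " (sensitivity ", signif(x$sensitivity, 4), ")\n", sep = "")
  cat("  non-episode patients: ", x$n_non_episode, ", false positives: ",
      x$n_false_positive_patients, " (specificity ",
      signif(x$specificity, 4), ")\n", sep = "")
  cat("  stage confusion (target rows x detected cols):\n")
  print(x$confusion)
  invisible(x)
}
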