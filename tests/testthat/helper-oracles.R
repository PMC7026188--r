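# Independent oracles and random-input generators for property tests.
# These deliberately avoid the package's production code paths: staging is
# re-derived with plain if/else, baselines by a full scan over the whole
# history, and test statistics from their textbook formulas.

DAY <- 86400
T0 <- as.POSIXct("2012-07-01 00:00:00", tz = "UTC")

naive_stage <- function(r) {
  if (r < 1.5) 0L else if (r < 2) 1L else if (r < 3) 2L else 3L
}

# brute-force re-evaluation: for every measurement scan the patient's whole
# history, filter to the 365-day window [t - 365d, t), take the minimum or
# fall back to the age reference limit
naive_evaluate <- function(m, reference = default_reference_table()) {
  m <- m[order(m$patient_id, m$measured_at, m$creatinine_umol_l), ]
  n <- nrow(m)
  baseline <- numeric(n); source <- character(n)
  ratio <- numeric(n); stage <- integer(n); has_prior <- logical(n)
  for (i in seq_len(n)) {
    others <- which(m$patient_id == m$patient_id[i] & seq_len(n) != i)
    w <- others[m$measured_at[others] >= m$measured_at[i] - 365 * DAY &
                  m$measured_at[others] < m$measured_at[i]]
    if (length(w) > 0) {
      baseline[i] <- min(m$creatinine_umol_l[w])
      source[i] <- "prior_minimum"
      has_prior[i] <- TRUE
    } else {
      baseline[i] <- upper_reference_limit(m$age_days[i], m$sex[i], reference)
      source[i] <- "reference_upper_limit"
    }
    ratio[i] <- m$creatinine_umol_l[i] / baseline[i]
    stage[i] <- naive_stage(ratio[i])
  }
  cbind(m, data.frame(baseline = baseline, source = source, ratio = ratio,
                      stage = stage, has_prior = has_prior))
}

# random multi-patient cohort spanning the lookback boundary; ages constant
# per patient, values scaled so that alerts and both baseline sources occur
random_cohort <- function(n_patients, seed, max_meas = 8) {
  set.seed(seed)
  rows <- lapply(seq_len(n_patients), function(i) {
    k <- sample(0:max_meas, 1)
    if (k == 0) return(NULL)
    age <- sample(29:6569, 1)
    tibble::tibble(
      patient_id = sprintf("r%03d", i),
      measured_at = T0 + runif(k, -500, 180) * DAY,
      creatinine_umol_l = round(runif(k, 10, 160), 1),
      age_days = age, sex = sample(c("any", "male", "female"), 1),
      centre = sample(c("C1", "C2", "C3"), 1))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      patient_id = "r001", measured_at = T0,
      creatinine_umol_l = 50, age_days = 1000, sex = "any", centre = "C1")
  }
  out
}

# two-row age-only reference table used throughout the reference tests
two_band_table <- function() {
  reference_table(data.frame(
    age_min_days = c(29, 365), age_max_days = c(365, 6570),
    sex = "any", upper_limit_umol_l = c(40, 100)))
}

# textbook Pearson chi-squared from scratch
direct_chisq <- function(x) {
  E <- outer(rowSums(x), colSums(x)) / sum(x)
  stat <- sum((x - E)^2 / E)
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

report_json_text <- function(rep) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_report_json(rep, f)
  paste(readLines(f), collapse = "\n")
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
perm_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_all <- apply(idx, 2, function(j) sum(r[j]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
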