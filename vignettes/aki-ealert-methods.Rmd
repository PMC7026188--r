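---
title: "Creatinine-ratio AKI e-alerting: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Creatinine-ratio AKI e-alerting: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akialert)
```

## The staging model

Acute kidney injury (AKI) e-alerting flags laboratory creatinine results
whose fold-rise over a patient-specific baseline crosses severity
thresholds. For a measurement with value $c$ (µmol/L) and resolved baseline
$b$, the ratio $r = c/b$ maps to a stage:

$$
\mathrm{stage}(r) =
\begin{cases}
\text{none} & r < 1.5 \\
1 & 1.5 \le r < 2 \\
2 & 2 \le r < 3 \\
3 & r \ge 3
\end{cases}
$$

All thresholds are lower-inclusive and upper-exclusive, which keeps the
stage-1 upper bound consistent with the stage-2 lower bound of exactly 2.
Urine output plays no part: this is a creatinine-only screen, which is known
to under-detect oliguric AKI.

The baseline $b$ is resolved per measurement:

1. **Prior minimum** — the lowest creatinine recorded for the same patient
   in the 365 days strictly before the index time $t$, i.e. over
   $[t - 365\,\mathrm{d}, t)$. The window excludes $t$ itself so a
   measurement can never serve as its own baseline, and so that same-day
   duplicates resolve deterministically (an earlier-timestamped same-day
   value is eligible; a value at the identical timestamp is not). A value at
   exactly $t - 365$ days is inside the window. Ties for the minimum are
   equivalent in value; the earliest timestamp is recorded as provenance.
2. **Reference fallback** — when no prior-year value exists, the age-specific
   upper reference limit of plasma creatinine is used as $b$. Such
   measurements never raise an alert unless they exceed 1.5 times the limit;
   instead, a value merely above the limit is annotated `above_reference`,
   keeping the "single high value" population visible without counting it as
   AKI.

Values that themselves raised an alert stay in the baseline pool by default:
the algorithm is defined on the plain 12-month minimum. Excluding them is
available as `exclude_alert_baseline = TRUE` for sensitivity analyses; it
can only raise later ratios.

Alerts are not de-duplicated into episodes: every alert-bearing measurement
counts. Cohort incidence is therefore reported both per measurement and per
patient (worst stage).

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| staging thresholds | fold-rise | 1.5 / 2 / 3 | consensus creatinine criteria |
| lookback window | days | 365 | twelve-month minimum definition |
| eligibility window | days of age | [29, 6570) | infancy floor to 18th birthday; both configurable |
| age bands | years | [0,1), [1,6), [6,11), [11,16), [16,18) | half-open, lower-inclusive, on 365-day years |
| rate rounding | decimals | 1 | matches audit-style reporting |
| mix rounding | decimals | 0 | stage mixes and splits as whole percents |

Percentages round half away from zero (`round_half_up()`); base R's
round-half-to-even disagrees with clinical-report arithmetic at ties. A rate
with a zero denominator is reported as undefined (`NA`, JSON `null`), never
as 0. A patient's age band is fixed at their first alert, so a patient
alerting across a birthday is counted in exactly one band; the band
boundaries use 365-day years so that an age of exactly 365 days falls in
the 1–<6y band.

The shipped reference table
(`inst/extdata/default_reference_intervals_synthetic.csv`) is **synthetic
and illustrative**: plausible paediatric upper limits per age band, age-only
because the algorithm description is age-only. Sex-specific rows are
supported (they take precedence over `any` rows at lookup) but none ship by
default. Replace the table via `read_reference_table()` for any real use;
validation enforces positive limits, non-overlap, and gap-free coverage of
the eligible age range.

## The comparison statistics

`chi_squared_test()` is the Pearson statistic on an $r \times c$ table with
margin-derived expected counts; the default is uncorrected because audit
reports rarely state a variant, and the Yates-corrected value is also
computed for 2×2 tables (it is never larger). The headline comparison —
alert rate among measurements with a prior baseline versus above-reference
rate among those without — builds its 2×2 from the four margins (events and
denominator minus events per arm). `mann_whitney_u()` reports the first
group's U with midrank ties; the p-value is exact by enumeration when both
groups have at most 10 untied observations, else the tie-corrected normal
approximation. `two_sample_t_test()` is the pooled-variance t with explicit
degenerate rules (zero pooled variance: equal means give $t=0, p=1$;
unequal means an infinite-statistic marker with $p=0$).

## What the synthetic generator emulates

`simulate_cohort()` produces a six-month hospital extract
(July–December 2012 window) with known ground truth:

- each patient draws an age band (default weights 20/39/17/19/5% across the
  five paediatric bands, mirroring the skew towards under-6s in hospital AKI
  cohorts), a sex, and a centre from a six-centre size distribution;
- a true baseline uniform at 40–80% of the age reference upper limit —
  healthy children sit well below the upper limit;
- with probability `lookback_coverage` (default 0.75), 1 + Poisson(1)
  pre-window measurements in the 180 days before the window, guaranteeing
  that every in-window measurement sees them inside its 365-day lookback;
- Poisson(`measurement_rate` = 3) in-window measurements at uniform times;
- with probability `episode_prevalence` (default 0.1) one rectangular AKI
  episode of 3–10 days, during which latent values are multiplied by a
  factor drawn uniformly inside the target stage's ratio interval
  (stage 1: [1.5, 2), stage 2: [2, 3), stage 3: [3, 6]); the target stage
  follows a 62/16/22 mix. An episode always receives at least one in-window
  measurement (the midpoint is added if the Poisson times missed the
  interval), so "episode present" coincides with "episode sampled";
- multiplicative lognormal noise with coefficient of variation `noise_cv`
  (default 0.05, typical of enzymatic creatinine assays), mean-corrected so
  the expected value equals the latent value; `noise_cv = 0` disables noise
  exactly. Noise is multiplicative because creatinine is positive and
  right-skewed; additive Gaussian noise could produce non-positive values
  at infant concentrations.

Two deliberate generator choices: ages are drawn from 60 days upward (the
eligibility floor is 29 days) so that every patient *can* carry prior-year
history while all measurement ages stay eligible; and each patient's draws
come from a seed derived from the configuration seed plus the patient index,
with all quantities drawn whether or not they are used. The latter makes
cohorts byte-reproducible and gives a clean coupling: raising
`episode_prevalence` with everything else fixed only switches episodes on,
never perturbing other patients.

What the generator does **not** emulate: physiological creatinine
trajectories (episodes are rectangles, not ramps — a ramped profile is the
obvious extension), chronic kidney disease drift, assay recalibration,
admission structure, or any correlation between illness severity and
measurement frequency. Passing the recovery tests therefore shows the
*algorithmic* chain is correct (baseline resolution, staging, aggregation),
not that the pipeline's operating characteristics transfer to real hospital
data, where baselines drift and measurement timing is informative.

Ground truth is returned alongside the extract, and two evaluation tools
close the loop: `latent_stream()` stages the noise-free latent series (the
designed-detectability oracle), and `scorecard()` reports patient-level
sensitivity and specificity of episode detection plus a target-versus-
detected stage confusion matrix, where detection means an alert inside the
episode interval.

## Numerical and engineering choices

- The production evaluator computes each patient's rolling 365-day prior
  minimum with a monotonic-deque sliding-window algorithm (linear per
  patient); the test suite checks it exactly against a naive full-scan
  re-evaluation, and results are invariant to input row order.
- Timestamps are UTC POSIXct; a day is 86,400 s and the window exactly 365
  days. CSV output prints ISO-8601 (`%Y-%m-%dT%H:%M:%SZ`).
- Unusable extract rows (bad timestamp, non-positive value, ineligible age,
  unknown sex) are diverted to a rejects table with one reason each;
  processed plus rejected always equals the input row count.
- Report JSON serialisation is deterministic: identical inputs give
  byte-identical `report.json`, and identical configurations byte-identical
  simulation CSVs. The run manifest records package version, settings and
  input checksums, and contains no timestamps.

## Validation problem sizes

The shipped test-suite checks run at sizes chosen to finish quickly while
still exercising every path: exact oracle equivalence on 100 random cohorts
of 3–30 patients spanning the lookback boundary; noise-free full-lookback
recovery on cohorts of 150–300 patients at 25–30% episode prevalence; and
detection-rate recovery pooled over 20 seeded cohorts of 1,000 patients at
10% prevalence and 5% noise, compared to the latent-truth oracle within
three binomial standard errors of the pooled detection fraction. The
acceptance script repeats the recovery analyses at 10 × 500 patients.

## Known limitations

- The published headline incidence of such audits can mix denominators
  (alerts over all measurements versus over baseline-covered measurements);
  the report therefore always prints both rates, computed from its own
  counts, and leaves reconciling externally printed headline figures to the
  reader.
- The two-window NHS algorithm variant (separate short- and long-horizon
  reference values) is out of scope; only the single 12-month lowest-value
  baseline is implemented.
- Age for the reference fallback is age at measurement, not at admission.
- The default reference limits are illustrative; results on real data are
  meaningful only with locally validated limits.
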