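#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves moving away from zero,
#' the convention used for every percentage this package reports. Base R's
#' [round()] rounds halves to even, which disagrees with clinical-report
#' arithmetic at ties such as 26.5.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(0.5)          # 1
#' round_half_up(-0.5)         # -1
#' round_half_up(12.36, 1)     # 12.4
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage with protected denominator: zero denominator -> NA, never 0
pct <- function(num, den, digits = 1) {
  if (length(den) != 1 || is.na(den) || den == 0) {
    return(rep(NA_real_, length(num)))
  }
  round_half_up(100 * num / den, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seconds in the 365-day baseline lookback window
.window_secs <- 365 * 86400

# default eligibility bounds, in days of age
.age_min_default <- 29L
.age_max_default <- 18L * 365L

.sex_levels <- c("any", "male", "female")

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}
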