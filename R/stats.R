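#' Pearson chi-squared test of a contingency table
#'
#' Pearson's statistic on an r x c table of counts, with expected counts from
#' the row/column margins, `(r-1)(c-1)` degrees of freedom and the upper-tail
#' chi-squared p-value. The Yates continuity correction is applied only when
#' `correct = TRUE` and the table is 2 x 2; the corrected statistic is never
#' larger than the uncorrected one.
#'
#' @param counts Matrix (or coercible) of non-negative counts, at least
#'   2 x 2, with a positive grand total.
#' @param correct Apply the continuity correction (2 x 2 tables only).
#' @return List with `statistic`, `df`, `p_value`, `method`.
#' @examples
#' chi_squared_test(matrix(c(10, 10, 10, 10), 2))$p_value  # 1
#' @export
chi_squared_test <- function(counts, correct = FALSE) {
  x <- as.matrix(counts)
  abort_if(!is.numeric(x) || anyNA(x) || any(x < 0),
           "counts must be non-negative numbers")
  abort_if(nrow(x) < 2 || ncol(x) < 2,
           "contingency table needs at least 2 rows and 2 columns")
  abort_if(sum(x) <= 0, "contingency table has zero grand total")
  abort_if(any(rowSums(x) == 0) || any(colSums(x) == 0),
           "degenerate contingency table: a row or column margin is zero")
  correct <- isTRUE(correct) && all(dim(x) == 2)
  ht <- suppressWarnings(stats::chisq.test(x, correct = correct))
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       method = if (correct) "pearson_chi_squared_yates" else
         "pearson_chi_squared")
}

#' Mann-Whitney U test for two independent samples
#'
#' Reports the U statistic for the first group (rank sums with midranks for
#' ties) and a two-sided p-value: by exact enumeration when both groups have
#' at most `exact_max` observations and there are no ties, otherwise the
#' normal approximation with the tie-corrected variance.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param exact_max Largest per-group size for the exact p-value (default 10).
#' @return List with `U`, `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$U  # 4.5
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 10) {
  abort_if(length(group_a) == 0 || length(group_b) == 0,
           "both groups must be non-empty")
  abort_if(!is.numeric(group_a) || !is.numeric(group_b) ||
             anyNA(group_a) || anyNA(group_b),
           "groups must be numeric with no missing values")
  tied <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !tied && length(group_a) <= exact_max && length(group_b) <= exact_max
  ht <- suppressWarnings(stats::wilcox.test(
    group_a, group_b, exact = exact, correct = FALSE))
  list(U = unname(ht$statistic),
       p_value = unname(ht$p.value),
       method = if (exact) "exact" else "normal_approximation")
}

#' Pooled-variance two-sample t-test
#'
#' Independent-samples t-test with pooled variance and a two-tailed p-value.
#' Degenerate inputs are resolved explicitly: when the pooled variance is
#' zero, equal means give `t = 0, p = 1` and unequal means give an infinite
#' statistic with `p = 0`.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @return List with `t`, `df`, `p_value`.
#' @export
two_sample_t_test <- function(group_a, group_b) {
  abort_if(length(group_a) < 2 || length(group_b) < 2,
           "both groups need at least 2 observations")
  abort_if(!is.numeric(group_a) || !is.numeric(group_b) ||
             anyNA(group_a) || anyNA(group_b),
           "groups must be numeric with no missing values")
  df <- length(group_a) + length(group_b) - 2
  pooled <- ((length(group_a) - 1) * stats::var(group_a) +
               (length(group_b) - 1) * stats::var(group_b)) / df
  if (pooled == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = df, p_value = 1))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = df, p_value = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
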