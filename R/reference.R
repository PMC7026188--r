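#' Age-indexed upper reference limits for plasma creatinine
#'
#' An `aki_reference_table` holds upper reference limits of plasma creatinine
#' (µmol/L) indexed by age in days, optionally stratified by sex. The table is
#' used in two places: as the fallback baseline for measurements with no
#' creatinine result in the preceding 12 months, and as the screen that flags
#' such measurements as "above reference" when they exceed the limit for the
#' patient's age.
#'
#' Age membership is half-open: an interval `[age_min_days, age_max_days)`
#' contains an age `a` when `age_min_days <= a < age_max_days`. Within each
#' sex category the intervals must be non-overlapping, and the `any` rows (or,
#' when no `any` rows exist, each of the `male` and `female` sets) must cover
#' the eligible age range `[age_min, age_max)` with no gaps.
#'
#' @param x A data frame with columns `age_min_days`, `age_max_days`, `sex`
#'   (one of `"any"`, `"male"`, `"female"`) and `upper_limit_umol_l`.
#' @param age_min,age_max Eligible age range in days that the table must
#'   cover (defaults: 29 days and 18 years).
#' @return A validated tibble of class `aki_reference_table`, ordered by sex
#'   and `age_min_days`.
#' @seealso [upper_reference_limit()], [read_reference_table()],
#'   [default_reference_table()]
#' @examples
#' reference_table(data.frame(
#'   age_min_days = c(29, 365), age_max_days = c(365, 6570),
#'   sex = "any", upper_limit_umol_l = c(40, 100)
#' ))
#' @export
reference_table <- function(x, age_min = .age_min_default, age_max = .age_max_default) {
  abort_if(!is.data.frame(x), "reference table must be a data frame")
  need <- c("age_min_days", "age_max_days", "sex", "upper_limit_umol_l")
  missing_cols <- setdiff(need, names(x))
  abort_if(length(missing_cols) > 0,
           paste0("reference table is missing columns: ",
                  paste(missing_cols, collapse = ", ")))
  tbl <- tibble::as_tibble(x[need])
  tbl$age_min_days <- as.numeric(tbl$age_min_days)
  tbl$age_max_days <- as.numeric(tbl$age_max_days)
  tbl$sex <- tolower(as.character(tbl$sex))
  tbl$upper_limit_umol_l <- as.numeric(tbl$upper_limit_umol_l)

  abort_if(anyNA(tbl), "reference table contains missing or non-numeric entries")
  bad_sex <- !tbl$sex %in% .sex_levels
  abort_if(any(bad_sex),
           paste0("reference table rows with invalid sex: ",
                  paste(which(bad_sex), collapse = ", ")))
  bad_order <- tbl$age_min_days >= tbl$age_max_days
  abort_if(any(bad_order),
           paste0("reference table rows with age_min_days >= age_max_days: ",
                  paste(which(bad_order), collapse = ", ")))
  bad_limit <- tbl$upper_limit_umol_l <= 0
  abort_if(any(bad_limit),
           paste0("reference table rows with non-positive upper limit: ",
                  paste(which(bad_limit), collapse = ", ")))

  # non-overlap within every sex category; coverage for the resolving set
  for (s in unique(tbl$sex)) {
    check_intervals(tbl[tbl$sex == s, , drop = FALSE], s, check_cover = FALSE,
                    age_min = age_min, age_max = age_max)
  }
  if (any(tbl$sex == "any")) {
    check_intervals(tbl[tbl$sex == "any", , drop = FALSE], "any",
                    check_cover = TRUE, age_min = age_min, age_max = age_max)
  } else {
    for (s in c("male", "female")) {
      check_intervals(tbl[tbl$sex == s, , drop = FALSE], s, check_cover = TRUE,
                      age_min = age_min, age_max = age_max)
    }
  }

  tbl <- tbl[order(tbl$sex, tbl$age_min_days), ]
  structure(tbl,
            age_min = age_min, age_max = age_max,
            class = c("aki_reference_table", class(tbl)))
}

# overlap/gap validation for the rows of one sex category
check_intervals <- function(rows, sex, check_cover, age_min, age_max) {
  if (nrow(rows) == 0) {
    abort_if(check_cover,
             paste0("reference table has no rows for sex '", sex,
                    "' but coverage of [", age_min, ", ", age_max,
                    ") days is required"))
    return(invisible(TRUE))
  }
  idx <- order(rows$age_min_days)
  lo <- rows$age_min_days[idx]
  hi <- rows$age_max_days[idx]
  if (nrow(rows) > 1) {
    overlap <- which(lo[-1] < hi[-length(hi)])
    abort_if(length(overlap) > 0,
             paste0("overlapping reference intervals for sex '", sex,
                    "' between rows ", idx[overlap[1]], " and ",
                    idx[overlap[1] + 1],
                    " (ages ", lo[overlap[1] + 1], "-", hi[overlap[1]], " days)"))
  }
  if (check_cover) {
    abort_if(lo[1] > age_min,
             paste0("reference table for sex '", sex, "' does not cover ages ",
                    age_min, "-", lo[1], " days"))
    abort_if(hi[length(hi)] < age_max,
             paste0("reference table for sex '", sex, "' does not cover ages ",
                    hi[length(hi)], "-", age_max, " days"))
    if (nrow(rows) > 1) {
      gap <- which(lo[-1] > hi[-length(hi)])
      abort_if(length(gap) > 0,
               paste0("gap in reference intervals for sex '", sex,
                      "' between ages ", hi[gap[1]], " and ", lo[gap[1] + 1],
                      " days (rows ", idx[gap[1]], " and ", idx[gap[1] + 1], ")"))
    }
  }
  invisible(TRUE)
}

#' Read a reference-interval table from CSV or JSON
#'
#' The CSV must have the header
#' `age_min_days,age_max_days,sex,upper_limit_umol_l`; a JSON file must hold
#' an array of objects with the same field names.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @inheritParams reference_table
#' @return A validated [reference_table()].
#' @export
read_reference_table <- function(path, age_min = .age_min_default,
                                 age_max = .age_max_default) {
  abort_if(!file.exists(path), paste0("reference table not found: ", path))
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    readr::read_csv(path, col_types = readr::cols(
      age_min_days = "d", age_max_days = "d",
      sex = "c", upper_limit_umol_l = "d"
    ), progress = FALSE)
  }
  reference_table(x, age_min = age_min, age_max = age_max)
}

#' Built-in illustrative reference table
#'
#' Returns the age-only upper-limit table shipped with the package. The
#' limits are plausible paediatric values chosen for demonstration and
#' testing; they are synthetic, not taken from any clinical reference source,
#' and must be replaced with locally validated limits for any real use.
#'
#' @return An [reference_table()] covering ages 29 days to 18 years.
#' @export
default_reference_table <- function() {
  path <- system.file("extdata", "default_reference_intervals_synthetic.csv",
                      package = "akialert", mustWork = TRUE)
  read_reference_table(path)
}

#' Look up the upper reference limit for an age
#'
#' Resolves each (age, sex) pair to the unique interval containing the age.
#' Rows specific to the patient's sex take precedence over `sex = "any"`
#' rows; when the table is age-only every lookup resolves through the `any`
#' rows.
#'
#' @param age_days Numeric vector of ages in days.
#' @param sex Character vector (recycled) of `"any"`, `"male"` or `"female"`.
#' @param table An [reference_table()].
#' @return Numeric vector of upper limits in µmol/L.
#' @examples
#' tbl <- reference_table(data.frame(
#'   age_min_days = c(29, 365), age_max_days = c(365, 6570),
#'   sex = "any", upper_limit_umol_l = c(40, 100)
#' ))
#' upper_reference_limit(c(200, 365), "any", tbl)  # 40 100
#' @export
upper_reference_limit <- function(age_days, sex = "any",
                                  table = default_reference_table()) {
  abort_if(!inherits(table, "aki_reference_table"),
           "table must be built with reference_table() or read_reference_table()")
  abort_if(!is.numeric(age_days) || anyNA(age_days),
           "age_days must be numeric with no missing values")
  sex <- rep_len(tolower(as.character(sex)), length(age_days))
  abort_if(!all(sex %in% .sex_levels),
           "sex must be one of 'any', 'male', 'female'")

  out <- rep(NA_real_, length(age_days))
  for (s in unique(sex)) {
    pick <- sex == s
    rows <- table[table$sex == s, , drop = FALSE]
    hit <- match_interval(age_days[pick], rows)
    # fall back to the sex = any rows where no sex-specific interval matched
    if (s != "any") {
      any_rows <- table[table$sex == "any", , drop = FALSE]
      miss <- is.na(hit)
      if (any(miss)) hit[miss] <- match_interval(age_days[pick][miss], any_rows)
    }
    out[pick] <- hit
  }
  bad <- is.na(out)
  abort_if(any(bad),
           paste0("age outside reference table coverage: ",
                  paste(utils::head(age_days[bad], 5), collapse = ", "),
                  " days"))
  out
}

# vectorized half-open interval lookup over one sex category's rows
match_interval <- function(ages, rows) {
  if (nrow(rows) == 0 || length(ages) == 0) return(rep(NA_real_, length(ages)))
  idx <- findInterval(ages, rows$age_min_days)
  ok <- idx >= 1 & idx <= nrow(rows)
  ok[ok] <- ages[ok] < rows$age_max_days[idx[ok]]
  out <- rep(NA_real_, length(ages))
  out[ok] <- rows$upper_limit_umol_l[idx[ok]]
  out
}

#' @export
print.aki_reference_table <- function(x, ...) {
  cat("Creatinine upper reference limits (",
      attr(x, "age_min"), "-", attr(x, "age_max"), " days)\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
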