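#' Cohort CSV input and output
#'
#' The cohort travels as a comma-separated, UTF-8, dot-decimal CSV with the
#' header
#' `subject_id,sex,age_months,whole_brain_mL,rostrum,genu,rostral_body,`
#' `anterior_midbody,posterior_midbody,isthmus,splenium,total_cc`.
#' Reading validates every row (sex in male/female, age in (0, 300],
#' nonnegative areas, positive totals and brain volumes) and reports the
#' offending row and column on failure.
#'
#' @param path CSV file path.
#' @param cohort Cohort tibble.
#' @return `read_cohort_csv` returns a validated cohort tibble;
#'   `write_cohort_csv` returns `path` invisibly.
#' @name cohort_csv
NULL

#' @rdname cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "ccmorph_parse_error")
  }
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      sex = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ccmorph_parse_error")
  }
  cohort <- cohort[, COHORT_COLUMNS]
  validate_cohort(cohort, context = path)
  cohort
}

#' @rdname cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort[, COHORT_COLUMNS], path, progress = FALSE)
  invisible(path)
}

# Validate a cohort table; failures name the first offending row and column.
validate_cohort <- function(cohort, context = "cohort") {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0(context, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ccmorph_parse_error")
  }
  if (nrow(cohort) == 0) {
    abort(paste0(context, ": empty cohort"), class = "ccmorph_parse_error")
  }
  fail <- function(rows, col, why) {
    if (length(rows) > 0) {
      abort(sprintf("%s: row %d, column '%s': %s", context, rows[1], col,
                    why),
            class = c("ccmorph_parse_error", "ccmorph_input_error"))
    }
  }
  fail(which(!cohort$sex %in% c("male", "female")), "sex",
       "must be 'male' or 'female'")
  num_cols <- setdiff(COHORT_COLUMNS, c("subject_id", "sex"))
  for (cl in num_cols) {
    fail(which(!is.finite(cohort[[cl]])), cl, "non-numeric or missing")
  }
  fail(which(cohort$age_months <= 0 | cohort$age_months > 300),
       "age_months", "must lie in (0, 300]")
  fail(which(cohort$whole_brain_mL <= 0), "whole_brain_mL",
       "must be positive")
  for (cl in CC_REGIONS) {
    fail(which(cohort[[cl]] < 0), cl, "must be nonnegative")
  }
  fail(which(cohort$total_cc <= 0), "total_cc", "must be positive")
  invisible(cohort)
}
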