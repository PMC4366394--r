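#' Callosal-to-brain ratios
#'
#' Divides every subregion area (mm^2) and the total by the subject's
#' whole-brain volume (mL). With ~500 mm^2 of callosum and ~1200 mL of
#' brain the total ratio is of magnitude 0.4, the scale on which the
#' published sex comparisons are reported. By construction the total ratio
#' equals the sum of the subregion ratios for each subject.
#'
#' @param cohort Cohort tibble.
#' @return Tibble with `subject_id`, `sex`, `age_months` and the eight
#'   ratio columns (same names as the area columns).
#' @export
#' @examples
#' ratio_to_brain(generate_cohort(seed = 2))
ratio_to_brain <- function(cohort) {
  validate_cohort(cohort)
  if (any(cohort$whole_brain_mL <= 0)) {
    abort("whole-brain volume must be positive for every subject",
          class = "ccmorph_input_error")
  }
  out <- cohort[, c("subject_id", "sex", "age_months")]
  for (m in CC_MEASURES) {
    out[[m]] <- cohort[[m]] / cohort$whole_brain_mL
  }
  out
}

#' Rank-based sex comparison of brain-normalised ratios
#'
#' Runs a Mann-Whitney U test per measure on the callosal/brain ratios,
#' female versus male, so positive `Z` means larger ratios in females.
#'
#' @param cohort Cohort tibble containing both sexes.
#' @param continuity Continuity correction flag passed to
#'   [mann_whitney_u()].
#' @return Tibble: `measure`, `U`, `Z`, `p`, `undefined`.
#' @export
sex_ratio_tests <- function(cohort, continuity = FALSE) {
  ratios <- ratio_to_brain(cohort)
  if (length(unique(ratios$sex)) < 2) {
    abort("both sexes are required for a sex comparison",
          class = "ccmorph_input_error")
  }
  rows <- lapply(CC_MEASURES, function(m) {
    res <- mann_whitney_u(ratios[[m]][ratios$sex == "female"],
                          ratios[[m]][ratios$sex == "male"],
                          continuity = continuity)
    tibble(measure = m, U = res$U, Z = res$Z, p = res$p,
           undefined = res$undefined)
  })
  dplyr::bind_rows(rows)
}

#' Group summaries of areas and ratios
#'
#' Mean, SD and count per (measure, sex, age group) for the raw areas, and
#' per (measure, sex) for the brain-normalised ratios. Single-subject cells
#' report an SD of 0; empty cells are absent (count would be 0).
#'
#' @param cohort Cohort tibble.
#' @return A list with tidy tibbles `regions` (measure, sex, age_group, n,
#'   mean, sd) and `ratios` (measure, sex, n, mean, sd).
#' @export
#' @examples
#' summarize_groups(generate_cohort(seed = 5))$ratios
summarize_groups <- function(cohort) {
  validate_cohort(cohort)
  d <- cohort
  d$age_group <- assign_age_group(d$age_months)
  long <- tidyr::pivot_longer(
    d[, c("sex", "age_group", CC_MEASURES)],
    cols = dplyr::all_of(CC_MEASURES),
    names_to = "measure", values_to = "value"
  )
  regions <- long |>
    dplyr::group_by(.data$measure, .data$sex, .data$age_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
      .groups = "drop"
    )

  ratios <- ratio_to_brain(cohort)
  rlong <- tidyr::pivot_longer(
    ratios[, c("sex", CC_MEASURES)],
    cols = dplyr::all_of(CC_MEASURES),
    names_to = "measure", values_to = "value"
  )
  rsum <- rlong |>
    dplyr::group_by(.data$measure, .data$sex) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, sd(.data$value), 0),
      .groups = "drop"
    )
  list(regions = regions, ratios = rsum)
}

#' Flag summary cells whose total disagrees with the sum of its regions
#'
#' Internal-consistency check for summary tables: within each (sex,
#' age group) cell, the mean total callosal area must equal the sum of the
#' seven subregion means (linearity of the mean). Rows failing the check
#' beyond `tol` -- as happens with transcription errors in printed tables
#' -- are returned.
#'
#' @param region_summary A tibble like `summarize_groups()$regions`, with
#'   columns `measure`, `sex`, `age_group`, `mean`.
#' @param tol Allowed absolute discrepancy in mm^2 (default 0.1, generous
#'   for values printed to one decimal).
#' @return Tibble of offending cells: `sex`, `age_group`, `total_mean`,
#'   `region_sum`, `discrepancy`.
#' @export
flag_total_mismatch <- function(region_summary, tol = 0.1) {
  req <- c("measure", "sex", "age_group", "mean")
  if (!all(req %in% names(region_summary))) {
    abort("summary must have columns measure, sex, age_group, mean",
          class = "ccmorph_input_error")
  }
  wide <- tidyr::pivot_wider(
    region_summary[, req],
    names_from = "measure", values_from = "mean"
  )
  if (!all(c(CC_REGIONS, "total_cc") %in% names(wide))) {
    abort("summary must cover all seven subregions and total_cc",
          class = "ccmorph_input_error")
  }
  region_sum <- rowSums(as.matrix(wide[, CC_REGIONS]))
  out <- tibble(
    sex = wide$sex, age_group = wide$age_group,
    total_mean = wide$total_cc, region_sum = region_sum,
    discrepancy = wide$total_cc - region_sum
  )
  out[abs(out$discrepancy) > tol, ]
}
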