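#' Mean subregion area under the saturating growth model
#'
#' The synthetic cohort assumes each subregion's expected midsagittal area
#' follows a saturating-exponential rise with an optional quadratic decline
#' after a peak age:
#' \deqn{m(t) = A (1 - e^{-t/\tau}) - d \max(0, t - t_{peak})^2}
#' where `t` is age in months. The rise time-constant `tau` controls how
#' quickly the region approaches its asymptote `A` (mm\eqn{^2}); `t_peak`
#' (months) and `d` (mm\eqn{^2}/month\eqn{^2}) give the curve a unique
#' interior local maximum, mimicking the late-adolescent growth peaks seen in
#' callosal development.
#'
#' @param age_months Numeric vector of ages in months.
#' @param asymptote Asymptotic area `A` in mm^2 (> 0).
#' @param tau Rise time-constant in months (> 0).
#' @param t_peak Peak age in months (24-300), or `NA` for no post-peak
#'   decline.
#' @param decline Post-peak quadratic decline coefficient `d` in
#'   mm^2/month^2 (>= 0).
#' @return Numeric vector of expected areas (mm^2).
#' @export
#' @examples
#' growth_mean(c(6, 24, 120, 300), asymptote = 150, tau = 20)
growth_mean <- function(age_months, asymptote, tau, t_peak = NA_real_,
                        decline = 0) {
  stopifnot(is.numeric(age_months), asymptote > 0, tau > 0, decline >= 0)
  m <- asymptote * (1 - exp(-age_months / tau))
  if (!is.na(t_peak)) {
    m <- m - decline * pmax(0, age_months - t_peak)^2
  }
  m
}

#' Construct a growth model table
#'
#' A growth model is a tibble with one row per (region, sex) giving the
#' parameters of [growth_mean()] plus a multiplicative noise
#' coefficient-of-variation `cv`. All seven subregions must be present for
#' every sex in the model.
#'
#' @param region,sex,asymptote,tau Vectors, recycled to a common length.
#' @param t_peak Peak ages (months) or `NA`.
#' @param decline Post-peak decline coefficients (>= 0).
#' @param cv Lognormal noise coefficient of variation (>= 0).
#' @return A tibble of class `cc_growth_model`.
#' @export
growth_model <- function(region, sex, asymptote, tau, t_peak = NA_real_,
                         decline = 0, cv = 0.15) {
  model <- tibble(
    region = as.character(region), sex = as.character(sex),
    asymptote = as.numeric(asymptote), tau = as.numeric(tau),
    t_peak = as.numeric(t_peak), decline = as.numeric(decline),
    cv = as.numeric(cv)
  )
  validate_growth_model(model)
  class(model) <- c("cc_growth_model", class(model))
  model
}

validate_growth_model <- function(model) {
  required <- c("region", "sex", "asymptote", "tau", "t_peak", "decline", "cv")
  missing_cols <- setdiff(required, names(model))
  if (length(missing_cols) > 0) {
    abort(paste0("growth model lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ccmorph_config_error")
  }
  bad <- !(model$region %in% CC_REGIONS)
  if (any(bad)) {
    abort(paste0("unknown region(s) in growth model: ",
                 paste(unique(model$region[bad]), collapse = ", ")),
          class = "ccmorph_config_error")
  }
  if (any(!model$sex %in% c("male", "female"))) {
    abort("growth model sex must be 'male' or 'female'",
          class = "ccmorph_config_error")
  }
  if (any(model$asymptote <= 0) || any(model$tau <= 0) ||
      any(model$decline < 0) || any(model$cv < 0)) {
    abort("growth model requires asymptote > 0, tau > 0, decline >= 0, cv >= 0",
          class = "ccmorph_config_error")
  }
  tp <- model$t_peak[!is.na(model$t_peak)]
  if (any(tp < 24 | tp > 300)) {
    abort("t_peak must lie in [24, 300] months (or be NA)",
          class = "ccmorph_config_error")
  }
  if (anyDuplicated(model[, c("region", "sex")])) {
    abort("duplicated (region, sex) rows in growth model",
          class = "ccmorph_config_error")
  }
  # mean areas must stay positive over the whole 1-300 month range; with a
  # post-peak decline the minimum is at 300 months
  m300 <- growth_mean(300, model$asymptote, model$tau) -
    ifelse(is.na(model$t_peak), 0,
           model$decline * pmax(0, 300 - model$t_peak)^2)
  if (any(m300 <= 0)) {
    bad <- paste(model$region[m300 <= 0], model$sex[m300 <= 0],
                 sep = "/", collapse = ", ")
    abort(paste0("growth model mean area nonpositive at 300 months for: ",
                 bad),
          class = "ccmorph_config_error")
  }
  invisible(model)
}

#' Default sex-specific growth model
#'
#' Parameters are loose, order-of-magnitude calibrations to published group
#' means for a 1-300 month developmental cohort: a rapid rise over the first
#' two years (tau around 20 months), asymptotes per region between ~18 mm^2
#' (rostrum) and ~170 mm^2 (splenium), and mild post-peak declines placed in
#' late adolescence. They are synthetic stand-ins, not fitted estimates.
#'
#' @param cv Noise coefficient of variation applied to every stratum
#'   (default 0.15, in line with the dispersion of published group SDs).
#' @return A `cc_growth_model` tibble (14 rows).
#' @export
#' @examples
#' default_growth_model()
default_growth_model <- function(cv = 0.15) {
  male <- growth_model(
    region = CC_REGIONS, sex = "male",
    asymptote = c(18, 145, 85, 68, 60, 48, 172),
    tau = c(40, 22, 20, 22, 22, 24, 18),
    t_peak = c(240, 223, 233, 224, 209, 219, 212),
    decline = c(8e-4, 2e-3, 1.5e-3, 1e-3, 1e-3, 1e-3, 2e-3),
    cv = cv
  )
  female <- growth_model(
    region = CC_REGIONS, sex = "female",
    asymptote = c(17, 135, 82, 64, 59, 45, 168),
    tau = c(40, 22, 20, 22, 22, 24, 18),
    t_peak = c(132, 214, NA, 211, 243, NA, NA),
    decline = c(2e-4, 2e-3, 0, 1e-3, 1e-3, 0, 0),
    cv = cv
  )
  out <- dplyr::bind_rows(male, female)
  class(out) <- c("cc_growth_model", class(out))
  out
}

#' A growth model with identical parameters in every subregion
#'
#' Convenience constructor for validation studies (e.g. growth-peak recovery)
#' where the total callosal curve should inherit a single, well-defined
#' interior maximum. Each of the seven subregions, in both sexes, gets the
#' same parameters, so the total curve is `7 * growth_mean(...)`.
#'
#' @inheritParams growth_model
#' @return A `cc_growth_model` tibble (14 rows).
#' @export
flat_growth_model <- function(asymptote = 70, tau = 60, t_peak = 210,
                              decline = 0.004, cv = 0.05) {
  growth_model(
    region = rep(CC_REGIONS, 2),
    sex = rep(c("male", "female"), each = 7),
    asymptote = asymptote, tau = tau, t_peak = t_peak,
    decline = decline, cv = cv
  )
}

#' Default whole-brain volume model
#'
#' Whole-brain volume (mL) follows an exponential approach from a neonatal
#' volume to a sex-specific plateau, with lognormal noise. Males plateau
#' higher than females, which is what makes callosal/brain ratios slightly
#' larger in females even when raw callosal areas are similar.
#'
#' @param cv Noise coefficient of variation (default 0.08).
#' @return Tibble with one row per sex: `w_infinity`, `w_neonatal`, `tau`,
#'   `cv`.
#' @export
default_brain_model <- function(cv = 0.08) {
  tibble(
    sex = c("male", "female"),
    w_infinity = c(1400, 1270),
    w_neonatal = c(480, 450),
    tau = 28,
    cv = cv
  )
}

#' Cohort sampling design
#'
#' A design is a tibble with one row per recruitment cell: `sex`,
#' `age_group` (a free label), the number of subjects `n`, and the month
#' range `[age_min, age_max]` from which ages are drawn uniformly (integer
#' months).
#'
#' @return A tibble of class `cc_cohort_design`.
#' @name cohort_design
NULL

#' Default cohort design (114 subjects)
#'
#' Reproduces the cell sizes of the cross-sectional cohort the generator
#' emulates: males 19/18/17/7 and females 10/21/15/7 across infant, child,
#' adolescent and adult age groups (61 males, 53 females, 114 in total),
#' ages 1-300 months.
#'
#' @return A `cc_cohort_design` tibble (8 rows).
#' @export
#' @examples
#' default_cohort_design()
default_cohort_design <- function() {
  design <- tibble(
    sex = rep(c("male", "female"), each = 4),
    age_group = rep(c("infant", "child", "adolescent", "adult"), 2),
    n = c(19L, 18L, 17L, 7L, 10L, 21L, 15L, 7L),
    age_min = rep(c(1L, 25L, 121L, 216L), 2),
    age_max = rep(c(24L, 120L, 215L, 300L), 2)
  )
  class(design) <- c("cc_cohort_design", class(design))
  design
}

#' Uniform-age cohort design
#'
#' One cell per sex with ages drawn uniformly over a single month range.
#' Used for validation studies that need even age coverage.
#'
#' @param n_per_sex Subjects per sex.
#' @param age_min,age_max Month range (inclusive).
#' @return A `cc_cohort_design` tibble (2 rows).
#' @export
uniform_cohort_design <- function(n_per_sex = 200, age_min = 1,
                                  age_max = 300) {
  design <- tibble(
    sex = c("male", "female"),
    age_group = "all",
    n = as.integer(n_per_sex),
    age_min = as.integer(age_min),
    age_max = as.integer(age_max)
  )
  class(design) <- c("cc_cohort_design", class(design))
  design
}

validate_cohort_design <- function(design) {
  required <- c("sex", "age_group", "n", "age_min", "age_max")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort design lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ccmorph_config_error")
  }
  if (any(!design$sex %in% c("male", "female"))) {
    abort("design sex must be 'male' or 'female'",
          class = "ccmorph_config_error")
  }
  if (any(design$n < 0) || any(design$n != round(design$n))) {
    abort("design cell sizes must be nonnegative integers",
          class = "ccmorph_config_error")
  }
  if (any(design$age_min < 1) || any(design$age_max > 300) ||
      any(design$age_min > design$age_max)) {
    abort("design age ranges must satisfy 1 <= age_min <= age_max <= 300",
          class = "ccmorph_config_error")
  }
  invisible(design)
}
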