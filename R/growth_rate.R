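#' Construct a trajectory curve from explicit values
#'
#' Builds the `cc_curve` container used by [growth_change_rate()] and
#' [find_local_maxima()] from an explicit age grid and fitted values, e.g.
#' for trajectories smoothed elsewhere or for closed-form checks.
#'
#' @param age Strictly increasing numeric grid (months).
#' @param fitted Finite numeric values, same length.
#' @param sex,measure Optional stratum labels.
#' @return A `cc_curve`.
#' @export
#' @examples
#' curve <- trajectory_curve(0:10, 100 * 1.05^(0:10))
#' growth_change_rate(curve)$rate[1]
trajectory_curve <- function(age, fitted, sex = NULL, measure = NULL) {
  age <- as.numeric(age)
  fitted <- as.numeric(fitted)
  if (length(age) != length(fitted) || length(age) < 2) {
    abort("age and fitted must have equal length >= 2",
          class = "ccmorph_input_error")
  }
  if (any(diff(age) <= 0) || any(!is.finite(age)) || any(!is.finite(fitted))) {
    abort("age must be strictly increasing and values finite",
          class = "ccmorph_input_error")
  }
  structure(
    list(age = age, fitted = fitted, sex = sex, measure = measure,
         n = length(age), config = NULL),
    class = "cc_curve"
  )
}

#' Monthly growth-change rate of a fitted trajectory
#'
#' For each grid month `t` after the first, the rate is
#' \deqn{100 \times (v_t - v_{t-1}) / v_t}
#' i.e. the month-on-month change of the smoothed value expressed as a
#' percentage of the present month's value. Months where the present
#' fitted value is zero have an undefined rate and are flagged, not
#' dropped.
#'
#' @param curve A `cc_curve` from [lowess_fit()].
#' @return A tibble of class `cc_rate_series`: `sex`, `measure`,
#'   `age_months` (from the second grid point), `rate` (% per month, `NA`
#'   where undefined) and `undefined` (logical flag).
#' @export
#' @examples
#' fit <- lowess_fit(0:20, 100 * 1.05^(0:20), loess_config(alpha = 0.3,
#'                   iterations = 0))
#' head(growth_change_rate(fit))
growth_change_rate <- function(curve) {
  stopifnot(inherits(curve, "cc_curve"))
  v <- curve$fitted
  if (length(v) < 2) {
    abort("curve needs at least 2 grid points", class = "ccmorph_input_error")
  }
  present <- v[-1]
  past <- v[-length(v)]
  undefined <- present == 0
  rate <- ifelse(undefined, NA_real_, (present - past) / present * 100)
  out <- tibble(
    sex = curve$sex %||% NA_character_,
    measure = curve$measure %||% NA_character_,
    age_months = curve$age[-1],
    rate = rate,
    undefined = undefined
  )
  attr(out, "grid_range") <- range(curve$age)
  class(out) <- c("cc_rate_series", class(out))
  out
}

#' Detect growth-peak ages from a rate series
#'
#' A month `t` is a growth peak (local maximum of the fitted trajectory)
#' when its rate is strictly positive and the next month's rate is zero or
#' negative -- the positive-to-nonpositive zero crossing of the monthly
#' growth-change curve. Grid endpoints are never reported. Months flagged
#' undefined cannot form a crossing.
#'
#' @param series A `cc_rate_series` from [growth_change_rate()].
#' @return Numeric vector of peak ages (months), increasing; possibly
#'   empty.
#' @export
find_local_maxima <- function(series) {
  stopifnot(inherits(series, "cc_rate_series"))
  r <- series$rate
  k <- length(r)
  if (k < 2) return(numeric(0))
  cur <- r[-k]
  nxt <- r[-1]
  hit <- !is.na(cur) & !is.na(nxt) & cur > 0 & nxt <= 0
  ages <- series$age_months[-k][hit]
  grid_range <- attr(series, "grid_range")
  if (!is.null(grid_range)) {
    ages <- ages[ages > grid_range[1] & ages < grid_range[2]]
  }
  sort(ages)
}

#' Fit trajectories for every sex-by-measure stratum
#'
#' Fits a robust lowess curve, growth-change-rate series and growth-peak
#' detection for each of the 16 strata (2 sexes x 7 subregions + total).
#' Strata with fewer than 5 subjects are skipped with a warning.
#'
#' @param cohort Cohort tibble (see [generate_cohort()]).
#' @param config A [loess_config()].
#' @return An object of class `cc_trajectories` with tidy tibbles:
#'   `curves` (sex, measure, age_months, fitted), `rates` (sex, measure,
#'   age_months, rate, undefined), `peaks` (sex, measure, age_months), and
#'   `strata` (sex, measure, n, fitted flag).
#' @export
#' @examples
#' traj <- fit_all(generate_cohort(seed = 7))
#' traj$peaks
fit_all <- function(cohort, config = loess_config()) {
  validate_cohort(cohort)
  strata <- expand.grid(sex = c("male", "female"), measure = CC_MEASURES,
                        stringsAsFactors = FALSE)
  curves <- list()
  rates <- list()
  peaks <- list()
  info <- list()
  for (i in seq_len(nrow(strata))) {
    s <- strata$sex[i]
    mname <- strata$measure[i]
    sub <- cohort[cohort$sex == s, ]
    n_sub <- nrow(sub)
    if (n_sub < 5) {
      warn(sprintf("stratum %s/%s skipped: %d subject(s) < 5", s, mname,
                   n_sub))
      info[[i]] <- tibble(sex = s, measure = mname, n = n_sub,
                          fitted = FALSE)
      next
    }
    curve <- lowess_fit(sub$age_months, sub[[mname]], config,
                        sex = s, measure = mname)
    rate <- growth_change_rate(curve)
    pk <- find_local_maxima(rate)
    curves[[i]] <- as_tibble(as.data.frame(curve))
    rates[[i]] <- rate
    if (length(pk) > 0) {
      peaks[[i]] <- tibble(sex = s, measure = mname, age_months = pk)
    }
    info[[i]] <- tibble(sex = s, measure = mname, n = n_sub, fitted = TRUE)
  }
  structure(
    list(
      curves = dplyr::bind_rows(curves),
      rates = dplyr::bind_rows(lapply(rates, as_tibble)),
      peaks = dplyr::bind_rows(peaks),
      strata = dplyr::bind_rows(info),
      config = config
    ),
    class = "cc_trajectories"
  )
}

#' @export
print.cc_trajectories <- function(x, ...) {
  cat(sprintf("<cc_trajectories> %d/%d strata fitted, %d growth peaks\n",
              sum(x$strata$fitted), nrow(x$strata), nrow(x$peaks)))
  invisible(x)
}
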