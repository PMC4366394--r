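#' Configuration for robust locally weighted regression
#'
#' @param alpha Smoothing span in (0, 1]: the fraction of observations in
#'   each local neighbourhood (default 0.75, the span used throughout the
#'   developmental analysis).
#' @param degree Local polynomial degree (0, 1 or 2; default 1, Cleveland's
#'   original robust lowess).
#' @param iterations Number of bisquare robustness reweighting iterations
#'   after the initial fit (default 4).
#' @param grid Optional integer evaluation grid in months; when `NULL` the
#'   fit is evaluated at every integer month between the youngest and oldest
#'   observed age.
#' @return A list of class `cc_loess_config`.
#' @export
#' @examples
#' loess_config(alpha = 0.5, iterations = 0)
loess_config <- function(alpha = 0.75, degree = 1, iterations = 4,
                         grid = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    abort("alpha must lie in (0, 1]", class = "ccmorph_config_error")
  }
  if (!degree %in% 0:2) {
    abort("degree must be 0, 1 or 2", class = "ccmorph_config_error")
  }
  if (!is.numeric(iterations) || iterations < 0 ||
      iterations != round(iterations)) {
    abort("iterations must be a nonnegative integer",
          class = "ccmorph_config_error")
  }
  if (!is.null(grid)) {
    grid <- as.numeric(grid)
    if (length(grid) < 2 || any(diff(grid) <= 0)) {
      abort("grid must be strictly increasing with >= 2 points",
            class = "ccmorph_config_error")
    }
  }
  structure(
    list(alpha = alpha, degree = as.integer(degree),
         iterations = as.integer(iterations), grid = grid),
    class = "cc_loess_config"
  )
}

#' Robust lowess trajectory fit
#'
#' Fits Cleveland-style robust locally weighted regression of area against
#' age and evaluates the smooth on an integer monthly grid. At each
#' evaluation age the `q = ceiling(alpha * n)` nearest observations (by
#' absolute age difference; distance ties are all included) are weighted by
#' the tricube kernel \eqn{w(z) = (1 - |z|^3)^3} with `z` the age distance
#' divided by the largest neighbourhood distance, and a weighted local
#' polynomial of the configured degree is evaluated at the target age.
#' Robustness iterations then reweight observations by the bisquare
#' \eqn{B(r) = (1 - (r / 6m)^2)^2} for `|r| < 6m` (zero otherwise), `m`
#' being the median absolute residual, and refit.
#'
#' @param ages Numeric vector of ages in months (>= 5 points).
#' @param values Numeric vector of areas (mm^2), same length.
#' @param config A [loess_config()].
#' @param sex,measure Optional stratum labels carried on the result.
#' @return An object of class `cc_curve`: `age` (grid), `fitted`, `sex`,
#'   `measure`, `n` (observations) and the `config` used.
#' @export
#' @examples
#' fit <- lowess_fit(0:20, 2 * (0:20) + 1, loess_config(iterations = 0))
#' max(abs(fit$fitted - (2 * fit$age + 1)))
lowess_fit <- function(ages, values, config = loess_config(),
                       sex = NULL, measure = NULL) {
  stopifnot(inherits(config, "cc_loess_config"))
  ages <- as.numeric(ages)
  values <- as.numeric(values)
  if (length(ages) != length(values)) {
    abort("ages and values must have the same length",
          class = "ccmorph_fit_error")
  }
  keep <- is.finite(ages) & is.finite(values)
  ages <- ages[keep]
  values <- values[keep]
  n <- length(ages)
  if (n < 5) {
    abort("lowess fit requires at least 5 finite observations",
          class = "ccmorph_fit_error")
  }
  if (length(unique(ages)) < 2) {
    abort("lowess fit requires at least 2 distinct ages",
          class = "ccmorph_fit_error")
  }
  grid <- config$grid %||% seq(ceiling(min(ages)), floor(max(ages)))
  q <- ceiling(config$alpha * n)

  robustness <- rep(1, n)
  if (config$iterations > 0) {
    for (it in seq_len(config$iterations)) {
      fitted_obs <- local_fit(ages, ages, values, robustness, q, config$degree)
      r <- values - fitted_obs
      m <- median(abs(r))
      scale <- median(abs(values)) + 1e-12
      if (m <= 1e-10 * scale) {
        # the bulk of the data is fitted exactly; keep those points and
        # reject any remaining gross outliers outright
        robustness <- as.numeric(abs(r) <= 1e-8 * scale)
        if (all(robustness == 0)) robustness <- rep(1, n)
        break
      }
      z <- r / (6 * m)
      robustness <- ifelse(abs(z) < 1, (1 - z^2)^2, 0)
    }
  }
  fitted <- local_fit(grid, ages, values, robustness, q, config$degree)

  structure(
    list(age = grid, fitted = fitted, sex = sex, measure = measure,
         n = n, config = config),
    class = "cc_curve"
  )
}

# Evaluate the weighted local polynomial fit at each x0 in `at`.
local_fit <- function(at, x, y, robustness, q, degree) {
  vapply(at, function(x0) {
    d <- abs(x - x0)
    dq <- sort(d, partial = q)[q]
    if (dq <= 0) {
      abort(sprintf("zero-spread neighbourhood at age %g", x0),
            class = "ccmorph_fit_error")
    }
    w <- (1 - pmin(d / dq, 1)^3)^3 * robustness
    if (sum(w) <= 0) {
      # all neighbourhood points robustness-rejected; fall back to tricube
      w <- (1 - pmin(d / dq, 1)^3)^3
    }
    if (degree == 0) {
      return(sum(w * y) / sum(w))
    }
    xc <- x - x0
    X <- if (degree == 1) cbind(1, xc) else cbind(1, xc, xc^2)
    fit <- lm.wfit(X, y, w)
    b0 <- fit$coefficients[1]
    if (is.na(b0)) sum(w * y) / sum(w) else unname(b0)
  }, numeric(1))
}

#' @export
print.cc_curve <- function(x, ...) {
  cat(sprintf("<cc_curve> %s/%s: %d obs, grid %g..%g months\n",
              x$sex %||% "?", x$measure %||% "?", x$n,
              min(x$age), max(x$age)))
  invisible(x)
}

#' @export
as.data.frame.cc_curve <- function(x, ...) {
  data.frame(sex = x$sex %||% NA_character_,
             measure = x$measure %||% NA_character_,
             age_months = x$age, fitted = x$fitted)
}
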