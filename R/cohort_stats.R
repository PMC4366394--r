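#' Developmental age-group assignment
#'
#' Groups follow the ages at peak brain volume used in developmental
#' morphometry: infants (age <= 2 y), children (2 y < age <= 10 y),
#' adolescents (10 y < age < 18 y) and adults (18 y <= age <= 25 y), with
#' years converted at 12 months/year (24, 120 and 216 months).
#'
#' @param age_months Numeric vector of ages in months, each in (0, 300].
#' @return Factor with levels `infant`, `child`, `adolescent`, `adult`.
#' @export
#' @examples
#' assign_age_group(c(24, 25, 215, 216))
assign_age_group <- function(age_months) {
  age_months <- as.numeric(age_months)
  if (anyNA(age_months) || any(age_months <= 0) || any(age_months > 300)) {
    abort("ages must lie in (0, 300] months", class = "ccmorph_input_error")
  }
  out <- ifelse(age_months <= 24, "infant",
                ifelse(age_months <= 120, "child",
                       ifelse(age_months < 216, "adolescent", "adult")))
  factor(out, levels = c("infant", "child", "adolescent", "adult"))
}

#' Mixed-design repeated-measures ANOVA on the seven subregions
#'
#' Univariate mixed-model F tests with region (7 levels) as the
#' within-subject factor and sex and age group as between-subject factors.
#' Between-subject effects are tested against the subject-within-cells mean
#' square (denominator df `n - 8` for a full 2 x 4 design); region and its
#' interactions are tested against the region-by-subject error (denominator
#' df `6(n - 8)`). No sphericity correction is applied. Unbalanced cells
#' are handled with marginal (Type III, sum-to-zero contrasts) sums of
#' squares by default; Type II is available.
#'
#' @param cohort Cohort tibble; every subject needs all seven subregion
#'   values.
#' @param ss_type 3 (default) or 2, the sum-of-squares type passed to the
#'   underlying linear-model decomposition.
#' @return A tibble of class `cc_anova`: `effect`, `df1`, `df2`,
#'   `statistic` (F) and `p`.
#' @export
#' @examples
#' mixed_anova(generate_cohort(seed = 3))
mixed_anova <- function(cohort, ss_type = 3) {
  validate_cohort(cohort)
  if (!ss_type %in% c(2, 3)) {
    abort("ss_type must be 2 or 3", class = "ccmorph_config_error")
  }
  d <- as.data.frame(cohort)
  d$sex <- factor(d$sex, levels = c("male", "female"))
  # unused age-group levels are dropped (a cohort spanning only some of the
  # four groups is still a valid factorial); both sexes are always required
  d$age_group <- droplevels(assign_age_group(d$age_months))
  cells <- table(d$sex, d$age_group)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    nm <- paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
                sep = " x ", collapse = ", ")
    abort(paste0("empty design cell(s): ", nm),
          class = "ccmorph_analysis_error")
  }
  if (any(cells == 1)) {
    one <- which(cells == 1, arr.ind = TRUE)
    nm <- paste(rownames(cells)[one[, 1]], colnames(cells)[one[, 2]],
                sep = " x ", collapse = ", ")
    abort(paste0("design cell(s) with a single subject: ", nm),
          class = "ccmorph_analysis_error")
  }

  Y <- as.matrix(d[, CC_REGIONS])
  mlm <- lm(Y ~ sex * age_group, data = d,
            contrasts = list(sex = "contr.sum", age_group = "contr.sum"))
  idata <- data.frame(region = factor(CC_REGIONS, levels = CC_REGIONS))
  av <- car::Anova(mlm, idata = idata, idesign = ~region, type = ss_type)
  # summary() also computes sphericity-corrected epsilons, which are not
  # used here; silence its Huynh-Feldt clamping chatter
  uni <- withCallingHandlers(
    summary(av, multivariate = FALSE)$univariate.tests,
    warning = function(w) {
      if (grepl("eps > 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  uni <- uni[rownames(uni) != "(Intercept)", , drop = FALSE]
  out <- tibble(
    effect = rownames(uni),
    df1 = as.integer(uni[, "num Df"]),
    df2 = as.integer(uni[, "den Df"]),
    statistic = as.numeric(uni[, "F value"]),
    p = as.numeric(uni[, "Pr(>F)"])
  )
  class(out) <- c("cc_anova", class(out))
  out
}

#' Two-way between-subjects ANOVA on a single measure
#'
#' Sex-by-age-group factorial ANOVA on one column of the cohort (typically
#' `total_cc` or `whole_brain_mL`), with the same sum-of-squares handling
#' as [mixed_anova()].
#'
#' @inheritParams mixed_anova
#' @param response Column name of the response measure.
#' @return A `cc_anova` tibble.
#' @export
between_anova <- function(cohort, response = "total_cc", ss_type = 3) {
  validate_cohort(cohort)
  if (!response %in% names(cohort)) {
    abort(paste0("no column '", response, "' in cohort"),
          class = "ccmorph_input_error")
  }
  d <- as.data.frame(cohort)
  d$sex <- factor(d$sex, levels = c("male", "female"))
  d$age_group <- droplevels(assign_age_group(d$age_months))
  d$.y <- d[[response]]
  fit <- lm(.y ~ sex * age_group, data = d,
            contrasts = list(sex = "contr.sum", age_group = "contr.sum"))
  tab <- car::Anova(fit, type = ss_type)
  res_df <- tab[rownames(tab) == "Residuals", "Df"]
  keep <- !rownames(tab) %in% c("Residuals", "(Intercept)")
  out <- tibble(
    effect = rownames(tab)[keep],
    df1 = as.integer(tab$Df[keep]),
    df2 = as.integer(res_df),
    statistic = as.numeric(tab$`F value`[keep]),
    p = as.numeric(tab$`Pr(>F)`[keep])
  )
  class(out) <- c("cc_anova", class(out))
  out
}

#' Tukey-Kramer post hoc pairwise comparisons
#'
#' Studentized-range comparisons of group means with Kramer's adjustment
#' for unequal group sizes: the standard error of a pairwise difference is
#' `sqrt(MS_error / 2 * (1/n_i + 1/n_j))`. Significance is flagged at the
#' Bonferroni-gated threshold `p < strict_alpha` (default 0.001, the
#' correction for seven subregions applied to post hoc tests).
#'
#' @param values Numeric response vector.
#' @param groups Factor or vector of group labels, same length.
#' @param error_ms Error mean square to test against; defaults to the
#'   pooled within-group mean square of `values`.
#' @param error_df Error degrees of freedom (defaults to `n - k`).
#' @param strict_alpha Threshold for the `significant` flag.
#' @return Tibble with one row per pair: `group1`, `group2`, `diff`, `se`,
#'   `q`, `p`, `significant`.
#' @export
#' @examples
#' tukey_hsd(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
tukey_hsd <- function(values, groups, error_ms = NULL, error_df = NULL,
                      strict_alpha = 0.001) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) {
    abort("at least 2 groups are required", class = "ccmorph_input_error")
  }
  stopifnot(length(values) == length(groups))
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  if (is.null(error_ms)) {
    resid <- values - means[groups]
    error_df <- length(values) - k
    error_ms <- sum(resid^2) / error_df
  } else if (is.null(error_df)) {
    abort("error_df must accompany error_ms", class = "ccmorph_input_error")
  }
  pairs <- utils::combn(levels(groups), 2)
  res <- vapply(seq_len(ncol(pairs)), function(col) {
    i <- pairs[1, col]
    j <- pairs[2, col]
    diff <- means[[i]] - means[[j]]
    se <- sqrt(error_ms / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = k, df = error_df, lower.tail = FALSE)
    c(diff, se, q, p)
  }, numeric(4))
  tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = res[1, ], se = res[2, ], q = res[3, ],
    p = res[4, ], significant = res[4, ] < strict_alpha
  )
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' @param mean1,sd1,n1 Summary statistics of the first sample.
#' @param mean2,sd2,n2 Summary statistics of the second sample.
#' @return A list of class `cc_t_test`: `t`, `df` (`n1 + n2 - 2`),
#'   `p` (two-sided) and `pooled_sd`. When both SDs are zero and the means
#'   are equal, `t = 0` by convention.
#' @export
#' @examples
#' pooled_t_test(96.9, 86.4, 61, 115.9, 77.8, 53)
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) {
    abort("both samples need n >= 2", class = "ccmorph_input_error")
  }
  if (sd1 < 0 || sd2 < 0) {
    abort("standard deviations must be nonnegative",
          class = "ccmorph_input_error")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  delta <- mean1 - mean2
  if (sp2 == 0) {
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    t_stat <- delta / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  }
  structure(
    list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df),
         pooled_sd = sqrt(sp2)),
    class = "cc_t_test"
  )
}

#' @export
print.cc_t_test <- function(x, ...) {
  cat(sprintf("two-sample t = %.3f, df = %d, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' U is computed from midrank sums; `U_x + U_y = n1 * n2`. The reported
#' `Z` uses the tie-corrected variance
#' \deqn{\sigma_U^2 = \frac{n_1 n_2}{12}\left(N + 1 -
#'   \frac{\sum (t^3 - t)}{N (N - 1)}\right)}
#' and, by default, no continuity correction. When every value in both
#' samples is identical the variance is zero and `Z` is flagged undefined.
#'
#' @param x,y Numeric samples.
#' @param continuity Apply a 0.5 continuity correction to Z
#'   (default `FALSE`).
#' @return A list of class `cc_mwu`: `U` (for `x`), `U_other`, `Z`, `p`
#'   (two-sided normal approximation) and `undefined`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 3), c(2, 4))
mann_whitney_u <- function(x, y, continuity = FALSE) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) {
    abort("both samples must be nonempty", class = "ccmorph_input_error")
  }
  all_v <- c(x, y)
  r <- rank(all_v)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  n_tot <- n1 + n2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 *
    ((n_tot + 1) - tie_term / (n_tot * (n_tot - 1)))
  if (sigma2 <= 0) {
    return(structure(
      list(U = u1, U_other = u2, Z = NA_real_, p = NA_real_,
           undefined = TRUE),
      class = "cc_mwu"
    ))
  }
  num <- u1 - n1 * n2 / 2
  if (continuity) num <- num - sign(num) * 0.5
  z <- num / sqrt(sigma2)
  structure(
    list(U = u1, U_other = u2, Z = z, p = min(1, 2 * pnorm(-abs(z))),
         undefined = FALSE),
    class = "cc_mwu"
  )
}

#' @export
print.cc_mwu <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("Mann-Whitney U = %g; Z undefined (no variance)\n", x$U))
  } else {
    cat(sprintf("Mann-Whitney U = %g, Z = %.3f, p = %.4g\n", x$U, x$Z, x$p))
  }
  invisible(x)
}
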