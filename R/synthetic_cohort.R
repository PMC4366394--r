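#' Generate a synthetic developmental cohort
#'
#' Draws one record per requested subject. For a subject of age `t` the area
#' of each subregion is `growth_mean(t, ...)` for that (region, sex),
#' multiplied by lognormal noise with unit mean and the model's coefficient
#' of variation; the total callosal area is the exact sum of the seven
#' subregion areas. Whole-brain volume follows [default_brain_model()] with
#' its own multiplicative noise.
#'
#' Randomness is reproducible: one master `seed` governs the cohort, and each
#' subject draws from a stream derived from the master seed and the subject's
#' position in the design, so a subset of cells regenerates identically.
#'
#' @param design A cohort design tibble (see [default_cohort_design()]).
#' @param model A `cc_growth_model` (see [default_growth_model()]).
#' @param brain Whole-brain model tibble (see [default_brain_model()]).
#' @param seed Integer master seed.
#' @return A tibble with columns
#'   `subject_id, sex, age_months, whole_brain_mL,` the seven subregions,
#'   and `total_cc` (areas in mm^2, brain volume in mL).
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' table(cohort$sex)
generate_cohort <- function(design = default_cohort_design(),
                            model = default_growth_model(),
                            brain = default_brain_model(),
                            seed = 1L) {
  validate_cohort_design(design)
  validate_growth_model(model)
  if (!all(c("sex", "w_infinity", "w_neonatal", "tau", "cv") %in% names(brain))) {
    abort("brain model lacks required columns", class = "ccmorph_config_error")
  }
  for (s in unique(design$sex)) {
    have <- model$region[model$sex == s]
    if (!setequal(have, CC_REGIONS)) {
      abort(paste0("growth model incomplete for sex '", s, "'"),
            class = "ccmorph_config_error")
    }
  }

  n_total <- sum(design$n)
  rows <- vector("list", n_total)
  counter <- 0L
  for (cell in seq_len(nrow(design))) {
    s <- design$sex[cell]
    mod_s <- model[model$sex == s, ]
    mod_s <- mod_s[match(CC_REGIONS, mod_s$region), ]
    brn <- brain[brain$sex == s, ]
    for (k in seq_len(design$n[cell])) {
      counter <- counter + 1L
      with_subject_stream(seed, counter, {
        span <- design$age_max[cell] - design$age_min[cell] + 1L
        age <- design$age_min[cell] + sample.int(span, 1L) - 1L
        # as growth_mean(), vectorised over the 7 regions with per-region
        # t_peak (NA = no decline)
        mu <- mod_s$asymptote * (1 - exp(-age / mod_s$tau)) -
          ifelse(is.na(mod_s$t_peak), 0,
                 mod_s$decline * pmax(0, age - mod_s$t_peak)^2)
        areas <- mu * lognormal_noise(7L, mod_s$cv)
        w_mu <- brn$w_infinity - (brn$w_infinity - brn$w_neonatal) *
          exp(-age / brn$tau)
        w <- w_mu * lognormal_noise(1L, brn$cv)
        rows[[counter]] <- c(age = age, brain = w, areas)
      })
    }
  }

  mat <- do.call(rbind, rows)
  cohort <- tibble(
    subject_id = sprintf("S%03d", seq_len(n_total)),
    sex = rep(design$sex, design$n),
    age_months = as.numeric(mat[, 1]),
    whole_brain_mL = as.numeric(mat[, 2])
  )
  for (j in seq_along(CC_REGIONS)) {
    cohort[[CC_REGIONS[j]]] <- as.numeric(mat[, j + 2])
  }
  cohort$total_cc <- rowSums(mat[, 2 + seq_along(CC_REGIONS), drop = FALSE])
  cohort
}

# Run expr under a deterministic per-subject RNG stream, restoring the
# caller's RNG state afterwards.
with_subject_stream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  derived <- (abs(as.numeric(seed)) * 1103515245 + counter * 12345) %% 2147483647
  set.seed(as.integer(derived))
  eval.parent(substitute(expr))
}

# Unit-mean lognormal multiplicative noise with coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  cv <- rep_len(cv, n)
  out <- rep(1, n)
  pos <- cv > 0
  if (any(pos)) {
    sdlog <- sqrt(log(1 + cv[pos]^2))
    out[pos] <- exp(stats::rnorm(sum(pos), -sdlog^2 / 2, sdlog))
  }
  out
}
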