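#' Build a pipeline run configuration
#'
#' Collects every knob of the analysis into one validated list, suitable for
#' serialisation as JSON. Either `simulate = TRUE` (generate a cohort) or
#' `cohort_csv` (read one) must be chosen; masks are optional and, when
#' provided through a manifest, are parcellated into the cohort.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for every random draw.
#' @param simulate Generate a synthetic cohort (default `TRUE` when no
#'   `cohort_csv` is given).
#' @param cohort_csv Optional path to an input cohort CSV.
#' @param mask_manifest Optional CSV with columns `subject_id`, `file`
#'   (PNG or NIfTI mask path, relative paths resolved against the
#'   manifest's directory), `sex`, `age_months`, `whole_brain_mL` and
#'   optionally `spacing_mm` (for PNG); each mask is measured and the
#'   records are appended to (or form) the cohort.
#' @param design,model,brain Synthetic-cohort inputs (see
#'   [generate_cohort()]).
#' @param loess A [loess_config()].
#' @param ss_type ANOVA sum-of-squares type (2 or 3).
#' @param continuity Continuity correction for the rank-based sex tests.
#' @return A list of class `cc_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = is.null(cohort_csv),
                       cohort_csv = NULL, mask_manifest = NULL,
                       design = default_cohort_design(),
                       model = default_growth_model(),
                       brain = default_brain_model(),
                       loess = loess_config(), ss_type = 3,
                       continuity = FALSE) {
  if (!simulate && is.null(cohort_csv) && is.null(mask_manifest)) {
    abort("need a cohort source: simulate, cohort_csv or mask_manifest",
          class = "ccmorph_config_error")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
         cohort_csv = cohort_csv, mask_manifest = mask_manifest,
         design = design, model = model, brain = brain, loess = loess,
         ss_type = ss_type, continuity = continuity),
    class = "cc_run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate and/or load, optional mask parcellation, trajectory
#' fitting and cohort statistics, writing tidy CSVs plus a JSON manifest
#' (seed, configuration hash, package and R versions, stage warnings, and
#' every output file) into `config$out_dir`. Outputs are deterministic for
#' a given configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `cohort`, the `cc_trajectories`
#'   bundle, the statistics tables, collected `warnings`, and the manifest
#'   path.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(out_dir = tempfile("ccrun"), seed = 11)
#' res <- run_pipeline(cfg)
#' res$manifest
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cc_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  warnings <- character(0)
  note <- function(msg) {
    warnings <<- c(warnings, msg)
    warn(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "ccmorph_pipeline_error")
    })
  }
  emit <- function(x, file) {
    path <- file.path(config$out_dir, file)
    readr::write_csv(x, path, progress = FALSE)
    outputs <<- c(outputs, file)
    path
  }

  cohort <- NULL
  if (isTRUE(config$simulate)) {
    cohort <- stage("simulate", generate_cohort(
      design = config$design, model = config$model, brain = config$brain,
      seed = config$seed
    ))
  }
  if (!is.null(config$cohort_csv)) {
    loaded <- stage("load", read_cohort_csv(config$cohort_csv))
    cohort <- if (is.null(cohort)) loaded else
      dplyr::bind_rows(cohort, loaded)
  }
  if (!is.null(config$mask_manifest)) {
    measured <- stage("parcellate", measure_mask_manifest(config$mask_manifest))
    cohort <- if (is.null(cohort)) measured else
      dplyr::bind_rows(cohort, measured)
  } else {
    note("parcellation stage skipped: no masks given")
  }
  emit(cohort, "cohort.csv")

  traj <- withCallingHandlers(
    stage("trajectory", fit_all(cohort, config$loess)),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  emit(traj$curves, "curves.csv")
  emit(traj$rates, "rates.csv")
  emit(if (nrow(traj$peaks) > 0) traj$peaks else
    tibble(sex = character(), measure = character(),
           age_months = numeric()), "peaks.csv")

  summaries <- stage("stats", summarize_groups(cohort))
  emit(summaries$regions, "region_summary.csv")
  anova_tab <- NULL
  cells <- table(cohort$sex, assign_age_group(cohort$age_months))
  if (all(cells >= 2)) {
    anova_tab <- stage("stats", mixed_anova(cohort, ss_type = config$ss_type))
    emit(anova_tab, "anova.csv")
  } else {
    note("mixed ANOVA skipped: some sex-by-age cells have < 2 subjects")
  }
  ratio_tab <- NULL
  if (length(unique(cohort$sex)) == 2) {
    ratio_tab <- stage("stats", dplyr::left_join(
      summaries$ratios,
      sex_ratio_tests(cohort, continuity = config$continuity),
      by = "measure"
    ))
    emit(ratio_tab, "ratio_summary.csv")
  } else {
    note("sex ratio comparison skipped: single-sex cohort")
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ccmorph")),
    outputs = outputs,
    warnings = warnings
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(cohort = cohort, trajectories = traj,
                 summaries = summaries, anova = anova_tab,
                 ratio_tests = ratio_tab, warnings = warnings,
                 manifest = manifest_path))
}

# Measure every mask listed in a manifest CSV into cohort records.
measure_mask_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(paste0("no such mask manifest: ", manifest_path),
          class = "ccmorph_parse_error")
  }
  man <- readr::read_csv(manifest_path, show_col_types = FALSE,
                         progress = FALSE)
  req <- c("subject_id", "file", "sex", "age_months", "whole_brain_mL")
  missing_cols <- setdiff(req, names(man))
  if (length(missing_cols) > 0) {
    abort(paste0("mask manifest lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ccmorph_parse_error")
  }
  base <- dirname(manifest_path)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, man$file[i])
    mask <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      sp <- if ("spacing_mm" %in% names(man)) man$spacing_mm[i] else 1
      read_mask_png(f, spacing = sp)
    } else {
      read_mask_nifti(f)
    }
    measure_record(mask, man$whole_brain_mL[i], man$sex[i],
                   man$age_months[i], subject_id = man$subject_id[i])
  })
  dplyr::bind_rows(rows)
}
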