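#' Published reference summaries shipped with the package
#'
#' Group-level summary statistics (means, SDs, group sizes, and for the
#' ratios the reported rank-test Z and p values) from the published
#' cross-sectional developmental cohort of 114 subjects that the synthetic
#' generator emulates. These printed summaries are the only data the source
#' study deposited; the package uses them for internal-consistency checks
#' (e.g. [flag_total_mismatch()]) and as calibration anchors -- raw
#' subject-level data are not recoverable from them.
#'
#' @param which `"regions"` (mean area per measure, sex and age group) or
#'   `"ratios"` (mean callosal/brain ratio per measure and sex).
#' @return A tibble.
#' @export
#' @examples
#' reference_summaries("ratios")
reference_summaries <- function(which = c("regions", "ratios")) {
  which <- match.arg(which)
  file <- switch(which,
                 regions = "reference_region_means.csv",
                 ratios = "reference_ratio_means.csv")
  path <- system.file("extdata", file, package = "ccmorph")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
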