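#' Plot fitted developmental trajectories
#'
#' One panel per measure, fitted area against age with one line per sex;
#' optionally overlays the raw cohort points.
#'
#' @param traj A `cc_trajectories` bundle from [fit_all()].
#' @param cohort Optional cohort tibble for the scatter underlay.
#' @param measures Measures to show (default: all fitted).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj, cohort = NULL, measures = NULL) {
  stopifnot(inherits(traj, "cc_trajectories"))
  curves <- traj$curves
  if (!is.null(measures)) curves <- curves[curves$measure %in% measures, ]
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$age_months, y = .data$fitted,
                                    colour = .data$sex))
  if (!is.null(cohort)) {
    long <- tidyr::pivot_longer(
      cohort[, c("sex", "age_months", CC_MEASURES)],
      cols = dplyr::all_of(CC_MEASURES),
      names_to = "measure", values_to = "fitted"
    )
    if (!is.null(measures)) long <- long[long$measure %in% measures, ]
    p <- p + ggplot2::geom_point(data = long, alpha = 0.3, size = 0.7)
  }
  p +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "age (months)", y = expression(area ~ (mm^2)),
                  colour = NULL)
}

#' Plot monthly growth-change rates with detected peaks
#'
#' One panel per measure, rate against age with a zero reference line;
#' detected growth-peak ages are marked with vertical dashes.
#'
#' @inheritParams plot_trajectories
#' @return A ggplot object.
#' @export
plot_growth_rates <- function(traj, measures = NULL) {
  stopifnot(inherits(traj, "cc_trajectories"))
  rates <- traj$rates
  peaks <- traj$peaks
  if (!is.null(measures)) {
    rates <- rates[rates$measure %in% measures, ]
    peaks <- peaks[peaks$measure %in% measures, ]
  }
  p <- ggplot2::ggplot(rates,
                       ggplot2::aes(x = .data$age_months, y = .data$rate,
                                    colour = .data$sex)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line(linewidth = 0.6)
  if (nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(
      data = peaks,
      ggplot2::aes(xintercept = .data$age_months, colour = .data$sex),
      linetype = 2, alpha = 0.6
    )
  }
  p +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "age (months)", y = "growth change rate (%/month)",
                  colour = NULL)
}
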