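#' Boxplot of signed mating angles by species
#'
#' Mirrors the classic presentation of per-species copulation angles: one
#' box per species around a dashed zero line (symmetric posture), with
#' sample sizes printed under the boxes; optionally faceted by time point.
#'
#' @param angles Data frame with `species_code`, `angle_deg` and
#'   optionally `timepoint_label`.
#' @return A ggplot object.
#' @export
plot_angles_by_species <- function(angles) {
  stopifnot(all(c("species_code", "angle_deg") %in% names(angles)))
  p <- ggplot2::ggplot(angles,
                       ggplot2::aes(x = .data$species_code,
                                    y = .data$angle_deg)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "signed mating angle [deg]\n(+ = female's right)")
  if ("timepoint_label" %in% names(angles)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$timepoint_label))
  }
  p + ggplot2::theme_minimal()
}

#' Overlay of registered male-head landmarks
#'
#' After two-point registration every frame shares the female baseline
#' (P1 at the origin, P2 at (0, 1)); plotting all registered P3 positions
#' shows the scatter of male head placements around the female midline.
#' The y axis is flipped so the plot reads like the source images (y
#' down).
#'
#' @param registered Output of [bookstein_register()].
#' @return A ggplot object.
#' @export
plot_registered_landmarks <- function(registered) {
  p3 <- filter(registered, .data$landmark == "P3")
  ggplot2::ggplot(p3, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::annotate("point", x = c(0, 0), y = c(0, 1), shape = 3,
                      size = 3) +
    ggplot2::annotate("text", x = c(0, 0), y = c(-0.05, 1.05),
                      label = c("P1", "P2"), size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "registered x (female's right →)",
                  y = "registered y") +
    ggplot2::theme_minimal()
}

#' Trajectory of interval-summarised angles
#'
#' Mean tilt angle per minute after copulation start with +/- 1 sd
#' ribbons, as produced by [interval_summary()].
#'
#' @param intervals Output of [interval_summary()].
#' @return A ggplot object.
#' @export
plot_angle_trajectory <- function(intervals) {
  ggplot2::ggplot(intervals,
                  ggplot2::aes(x = .data$interval_min + 0.5,
                               y = .data$mean_deg)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_deg - .data$sd_deg,
                                      ymax = .data$mean_deg + .data$sd_deg),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time after copulation start [min]",
                  y = "mean tilt angle [deg]") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-species angle estimates
#'
#' @param object An `angle_test` object from [species_angle_test()].
#' @param ... Unused.
#' @return A ggplot object: species estimates with 95% Wald intervals.
#' @export
autoplot.angle_test <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate_deg,
                                  y = .data$species_code)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate_deg - 1.96 * .data$se,
      xmax = .data$estimate_deg + 1.96 * .data$se), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "species mean angle [deg] (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
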