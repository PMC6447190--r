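#' Bar plot of condition mean thresholds with between-subject CIs
#'
#' The condition-summary figure of the pipeline: per-condition mean 75%
#' thresholds as bars, with t-based between-subject confidence intervals
#' as error bars, World families in blue and Retina families in red
#' (controls lighter).
#'
#' @param thresholds Tibble with `participant`, `condition`, `family`,
#'   `speed_class`, `threshold_75`.
#' @param level Confidence level for the error bars.
#' @return A ggplot object.
#' @export
plot_thresholds <- function(thresholds, level = 0.95) {
  ci <- between_subject_ci(thresholds, threshold_75, condition, level = level)
  ci <- dplyr::left_join(ci, condition_grid(), by = "condition")
  fills <- c(
    "World" = "#2166ac", "WorldControl" = "#92c5de",
    "Retina" = "#b2182b", "RetinaControl" = "#f4a582"
  )
  order <- c("World-Fast", "World-Slow", "WorldControl-Fast", "WorldControl-Slow",
             "Retina-Fast", "Retina-Slow", "RetinaControl-Fast", "RetinaControl-Slow")
  ci$condition <- factor(ci$condition, levels = intersect(order, ci$condition))
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$condition, y = .data$mean,
                                   fill = .data$family)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.25
    ) +
    ggplot2::scale_fill_manual(values = fills, guide = "none") +
    ggplot2::labs(x = NULL, y = "75% proportion-speed-change threshold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' Speed-time plot of a retinal trace
#'
#' Cyclopean angular speed of the positive-offset line over the interval:
#' accelerating curves for World stimuli, step functions for Retina
#' stimuli, with the changepoint marked.
#'
#' @param object A `retinal_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.retinal_trace <- function(object, ...) {
  cyc <- dplyr::filter(as_tibble(object),
                       .data$channel == "cyclopean", .data$line == "right")
  ggplot2::ggplot(cyc, ggplot2::aes(x = .data$time_s,
                                    y = .data$speed_arcmin_per_s)) +
    ggplot2::geom_vline(xintercept = attr(object, "change_time_s"),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "Time (s)", y = "Retinal speed (arcmin/s)") +
    ggplot2::theme_minimal()
}
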