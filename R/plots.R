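# ggplot2 helpers for sessions, pipeline streams and fitted models.

#' Plot the raw streams of a session
#'
#' Accelerometer, gyroscope and pressure traces with activity segments
#' shaded, faceted by channel group.
#'
#' @param session A \code{har_session}.
#' @return A ggplot object.
#' @export
plot_session <- function(session) {
  imu_long <- tidyr::pivot_longer(session$imu, -"t",
                                  names_to = "channel", values_to = "value")
  imu_long$group <- ifelse(grepl("^a", imu_long$channel),
                           "accelerometer (m/s²)", "gyroscope (rad/s)")
  baro <- session$baro
  baro_long <- tibble::tibble(t = baro$t, channel = "p", value = baro$p,
                              group = "pressure (hPa)")
  dat <- dplyr::bind_rows(imu_long, baro_long)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$value,
                                         colour = .data$channel))
  if (!is.null(session$labels)) {
    p <- p + ggplot2::geom_rect(
      data = session$labels, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf, fill = .data$label),
      alpha = 0.12
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~group, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the tilt stream of a pipeline run
#'
#' The shortest-rotation tilt (degrees) over time, with detected walking
#' samples marked along the axis; the near-90-degree step between standing
#' and sedentary segments is the signature the posture node thresholds.
#'
#' @param pipeline A \code{har_pipeline} from \code{\link{run_pipeline}}.
#' @return A ggplot object.
#' @export
plot_tilt <- function(pipeline) {
  s <- pipeline$streams
  dat <- tibble::tibble(t = s$t, tilt_deg = s$tilt * 180 / pi, walking = s$b_walk)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$tilt_deg)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "#2c7fb8") +
    ggplot2::geom_rug(data = dat[dat$walking, ], sides = "b",
                      alpha = 0.05, colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "shortest-rotation tilt (deg)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.hmha
#' @export
autoplot.har_score <- function(object, ...) {
  pc <- tidyr::pivot_longer(object$per_class, c("sensitivity", "specificity"),
                            names_to = "metric", values_to = "value")
  pc$class <- factor(pc$class, levels = activity_levels())
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "%",
                  title = sprintf("kappa = %.3f, total sensitivity = %.1f%%",
                                  object$kappa, object$total_sensitivity)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a fitted hierarchy or a score report
#'
#' \code{autoplot.hmha} shows each node's chosen feature and threshold;
#' \code{autoplot.har_score} shows per-class sensitivity and specificity.
#'
#' @param object A fitted \code{hmha} model or \code{har_score}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmha <- function(object, ...) {
  td <- tidy(object)
  td$node <- factor(td$node, levels = rev(td$node))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$threshold, y = .data$node)) +
    ggplot2::geom_point(size = 3, colour = "#d95f02") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%s ≤ %.3g → %s",
                                                    .data$feature,
                                                    .data$threshold,
                                                    .data$left)),
                       vjust = -1, size = 3) +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(x = "threshold", y = NULL,
                  title = sprintf("hierarchical activity model (%s features)",
                                  object$config)) +
    ggplot2::theme_minimal()
}
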