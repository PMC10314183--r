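# ggplot2 displays -----------------------------------------------------------

#' @method autoplot flic_binned
#' @export
autoplot.flic_binned <- function(object, ...) {
  a <- binned_attrs(object)
  ylab <- if (isTRUE(a$normalized)) {
    paste0("events (normalised, ", a$norm_mode, ")")
  } else if (identical(a$func, "mean")) {
    "event rate (per sample)"
  } else {
    "events per bin"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_start, y = .data$value,
                                       group = interaction(.data$monitor,
                                                           .data$well))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' @method autoplot flic_periodogram
#' @export
autoplot.flic_periodogram <- function(object, ...) {
  thr <- if (nrow(object$peaks)) object$peaks$signif_threshold[1] else NA
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$period_h, y = .data$power,
                               group = interaction(.data$monitor, .data$well))) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "period (h)", y = "autocorrelation power") +
    ggplot2::theme_minimal()
}

#' @method autoplot flic_periodogram_summary
#' @export
autoplot.flic_periodogram_summary <- function(object, ...) {
  ggplot2::ggplot(object$mean_curve,
                  ggplot2::aes(x = .data$period_h, y = .data$mean_power,
                               colour = .data$condition,
                               fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_power - .data$sem,
                                      ymax = .data$mean_power + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$signif_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "period (h)", y = "mean autocorrelation power") +
    ggplot2::theme_minimal()
}

#' Plot an average daily activity profile
#'
#' @param profile Output of [daily_profile()].
#' @param schedule Optional [light_schedule()]; when given, the dark phase
#'   is shaded.
#' @return A ggplot object.
#' @export
plot_daily_profile <- function(profile, schedule = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$tod_h, y = .data$mean,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time of day (h)", y = "mean events per bin") +
    ggplot2::theme_minimal()
  if (!all(is.na(profile$error))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$error,
                   ymax = .data$mean + .data$error),
      width = 0, alpha = 0.5
    )
  }
  if (!is.null(schedule)) {
    on_h <- schedule$on_s / 3600
    off_h <- schedule$off_s / 3600
    shade <- if (on_h < off_h) {
      data.frame(xmin = c(0, off_h), xmax = c(on_h, 24))
    } else {
      data.frame(xmin = off_h, xmax = on_h)
    }
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.1
    )
  }
  p
}

#' Plot day/night event counts per condition
#'
#' @param day_night Output of [split_day_night()].
#' @return A ggplot object.
#' @export
plot_day_night <- function(day_night) {
  long <- tidyr::pivot_longer(day_night, c("day", "night"),
                              names_to = "phase", values_to = "events")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$events,
                                     fill = .data$phase)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "events") +
    ggplot2::theme_minimal()
}
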