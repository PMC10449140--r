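#' Plot a recording trace
#'
#' @param object A `bci_recording`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bci_recording <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$t, y = .data$v * 1e6)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "voltage (uV)",
                  title = sprintf("%s / %s", attr(object, "task"),
                                  attr(object, "filter_setup"))) +
    ggplot2::theme_minimal()
}

#' Plot a sliding-power scan with its extrema
#'
#' @param object A `bci_sliding_power`.
#' @param ... Unused.
#' @return A ggplot (log10 power axis with min/max lines).
#' @exportS3Method ggplot2::autoplot
autoplot.bci_sliding_power <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_s, y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = range(df$power), linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window start (s)", y = "window power (V^2)") +
    ggplot2::theme_minimal()
}

#' Plot an evoked average with its detected peak
#'
#' @param object A `bci_evoked`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bci_evoked <- function(object, ...) {
  ggplot2::ggplot(object$waveform,
                  ggplot2::aes(x = .data$time_ms, y = .data$v * 1e6)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::annotate("point", x = object$latency_ms,
                      y = object$c_max * 1e6, colour = "red") +
    ggplot2::labs(x = "time after stimulus (ms)", y = "evoked EEG (uV)",
                  subtitle = sprintf("c_max = %.1f uV at %.0f ms (n = %d)",
                                     object$c_max * 1e6, object$latency_ms,
                                     object$n_events)) +
    ggplot2::theme_minimal()
}

#' Plot group SNR vs SNR-wall results
#'
#' Bar pairs (mean +/- SD) of SNR and SNR-wall per task, faceted by filter
#' setup, starred where detection is significantly possible.
#'
#' @param object A `bci_group_result` (one or more rows).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bci_group_result <- function(object, ...) {
  long <- as_tibble(object) |>
    select("task", "filter_setup", "mean_snr_db", "sd_snr_db",
           "mean_wall_db", "sd_wall_db", "significant") |>
    tidyr::pivot_longer(cols = c("mean_snr_db", "mean_wall_db"),
                        names_to = "quantity", values_to = "mean_db") |>
    mutate(
      sd_db = ifelse(.data$quantity == "mean_snr_db",
                     .data$sd_snr_db, .data$sd_wall_db),
      quantity = ifelse(.data$quantity == "mean_snr_db", "SNR", "SNR-wall"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$task, y = .data$mean_db,
                                     fill = .data$quantity)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_db - .data$sd_db,
                   ymax = .data$mean_db + .data$sd_db),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::geom_text(
      data = dplyr::distinct(long, .data$task, .data$filter_setup,
                             .data$significant),
      ggplot2::aes(x = .data$task, y = Inf,
                   label = ifelse(.data$significant, "*", "")),
      vjust = 1.2, inherit.aes = FALSE, size = 6) +
    ggplot2::facet_wrap(~filter_setup) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "dB", fill = NULL) +
    ggplot2::theme_minimal()
}
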