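#' Plot a fitted PWV waveform
#'
#' Shows the fitted shared velocity waveform knots (with the periodic linear
#' interpolation drawn densely over one cardiac cycle) and, optionally, the
#' initial mean waveform for comparison.
#'
#' @param object a [pwv_fit()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pwv_fit <- function(object, ...) {
  tt <- seq(object$frame_times[1L],
            object$frame_times[1L] + object$period, length.out = 400L)
  dense <- tibble(time = tt, value = interp_waveform(object$model, tt))
  knots <- tibble(time = object$frame_times, value = object$V_hat)
  ggplot2::ggplot(dense, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(data = knots, color = "steelblue") +
    ggplot2::labs(
      x = "time (s)", y = "normalized velocity",
      title = sprintf("Fitted waveform, PWV = %.2f m/s (N = %d)",
                      object$pwv, object$n_cross_sections)) +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of cross-section waveforms by vascular depth
#'
#' Normalized waveforms colored by distance from the arterial root; the
#' systolic peak drifts later with depth, which is the delay signal the
#' estimator exploits.
#'
#' @param records cross-section tibble.
#' @param frame_times frame times in seconds; defaults to the attribute on
#'   `records`.
#' @param max_curves subsample at most this many waveforms for legibility.
#' @return A ggplot.
#' @export
plot_waveform_fan <- function(records, frame_times = NULL, max_curves = 100L) {
  frame_times <- frame_times %||% attr(records, "frame_times")
  if (is.null(frame_times)) stopf("supply `frame_times`")
  if (nrow(records) > max_curves)
    records <- records[round(seq(1L, nrow(records), length.out = max_curves)), ]
  long <- records |>
    dplyr::select("cs_id", "distance_mm", dplyr::matches("^v[0-9]+$")) |>
    tidyr::pivot_longer(dplyr::matches("^v[0-9]+$"),
                        names_to = "frame", values_to = "velocity") |>
    dplyr::mutate(time = frame_times[as.integer(sub("^v", "", .data$frame))])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$velocity,
                                     group = .data$cs_id,
                                     color = .data$distance_mm)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_color_viridis_c(name = "depth (mm)") +
    ggplot2::labs(x = "time (s)", y = "normalized velocity") +
    ggplot2::theme_minimal()
}

#' Profile-objective plot of the grid oracle
#'
#' @param object result of [profile_fit_oracle()].
#' @param fit optional [pwv_fit()] to mark on the profile.
#' @return A ggplot.
#' @export
plot_pwv_profile <- function(object, fit = NULL) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$pwv, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_pwv, linetype = 2,
                        color = "steelblue") +
    ggplot2::labs(x = "PWV (m/s)", y = "profiled objective") +
    ggplot2::theme_minimal()
  if (!is.null(fit))
    p <- p + ggplot2::geom_vline(xintercept = fit$pwv, color = "firebrick",
                                 linetype = 3)
  p
}
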