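# ggplot2 views of the main result types

#' Plot an event scatter (dwell time vs normalized amplitude)
#'
#' The standard resistive-pulse representation: each event is a dot at its
#' duration tau_off (log scale) and normalized blockade amplitude A/I0,
#' colored by outcome.
#'
#' @param object An event tibble (with `tau_off`, `amplitude`, `outcome`) or
#'   a `pipeline_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pipeline_result <- function(object, ...) {
  plot_event_scatter(object$events)
}

#' @rdname autoplot.pipeline_result
#' @param events Event tibble.
#' @export
plot_event_scatter <- function(events) {
  ggplot2::ggplot(events,
                  ggplot2::aes(x = .data$tau_off * 1e6, y = .data$amplitude,
                               colour = .data$outcome)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau[off] ~ (mu * s)), y = "A / I0",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dwell-time histogram with log-spaced bins
#'
#' @param events Event tibble with `tau_off`.
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_dwell_histogram <- function(events, bins = 30) {
  h <- event_histogram(events, bins = bins)
  ggplot2::ggplot(h, ggplot2::aes(x = sqrt(.data$lower * .data$upper) * 1e6,
                                  y = .data$count)) +
    ggplot2::geom_col(width = 0.08, fill = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau[off] ~ (mu * s)), y = "events") +
    ggplot2::theme_minimal()
}

#' Plot a current trace
#'
#' @param object A `bd_trajectory` run with `store_stride = 1`.
#' @param grid Its `force_current_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bd_trajectory <- function(object, grid, ...) {
  tr <- current_trace(object, grid)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$current)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "time (ns)", y = "current (pA)") +
    ggplot2::theme_minimal()
}

#' Plot relative-diffusivity profiles
#'
#' Centerline or cross-section profiles of the parallel and perpendicular
#' relative diffusivities of a field, the usual way to compare hindrance
#' models.
#'
#' @param object A `diffusivity_field`.
#' @param along `"z"` or `"r"`.
#' @param at Fixed coordinate of the other axis (nm).
#' @param values Coordinates to evaluate (nm).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diffusivity_field <- function(object, along = "z", at = 0,
                                       values = NULL, ...) {
  if (is.null(values)) {
    values <- if (along == "z") {
      seq(object$spec$z_bot - 3, object$spec$z_top + 3, length.out = 120)
    } else {
      seq(0, profile_radius(object$spec, at) * 0.98, length.out = 80)
    }
  }
  pr <- field_profile(object, along = along, at = at, values = values)
  xcol <- if (along == "z") "z" else "r"
  df <- tibble::tibble(
    x = rep(pr[[xcol]], 2),
    rel = c(pr$rel_parallel, pr$rel_perpendicular),
    component = rep(c("parallel", "perpendicular"), each = nrow(pr))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$rel,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = paste0(xcol, " (nm)"), y = "D / D0", colour = NULL) +
    ggplot2::theme_minimal()
}
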