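#' Raster plot of a simulation
#'
#' @param object A `tc_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tc_sim
#' @export
autoplot.tc_sim <- function(object, ...) {
  sp <- object$spikes
  sp$population <- object$cells$population[match(sp$id, object$cells$id)]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time, y = .data$id,
                                   colour = .data$population)) +
    ggplot2::geom_point(size = 0.3, shape = 16) +
    ggplot2::labs(x = "time (ms)", y = "cell", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a distance-probability profile with optional fits
#'
#' @param profile Profile tibble from [estimate_bin_probabilities()] or
#'   [average_across_instances()].
#' @param fits Optional named list of `tc_fit` objects to overlay.
#' @return A ggplot object.
#' @export
plot_bin_profile <- function(profile, fits = NULL) {
  p <- ggplot2::ggplot(profile[profile$present, ],
                       ggplot2::aes(x = .data$bin_center, y = .data$probability)) +
    ggplot2::geom_point(shape = 18, size = 3, colour = "darkgreen") +
    ggplot2::labs(x = "XZ distance (um)", y = "connection probability") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    d <- seq(0, max(profile$bin_center) + 25, length.out = 200)
    curves <- bind_rows(purrr::imap(fits, function(f, nm)
      tibble(distance = d, probability = predict(f, d), form = nm)))
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$distance, y = .data$probability,
                   colour = .data$form))
  }
  p
}

#' Plot a power spectral density on log-log axes
#'
#' @param psd Tibble with `freq`, `power` (from [lfp_psd()] or
#'   `oscillation_peak()$spectrum`).
#' @return A ggplot object.
#' @export
plot_psd <- function(psd) {
  ggplot2::ggplot(psd[psd$freq > 0 & psd$power > 0, ],
                  ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power") +
    ggplot2::theme_minimal()
}

#' Plot placements in the XZ or XY plane
#'
#' @param cells Cell tibble.
#' @param plane `"xy"` (side view, depth on the vertical axis) or `"xz"` (top
#'   view).
#' @return A ggplot object.
#' @export
plot_placements <- function(cells, plane = c("xy", "xz")) {
  plane <- match.arg(plane)
  yvar <- if (plane == "xy") "y" else "z"
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data[[yvar]],
                                           colour = .data$population)) +
    ggplot2::geom_point(size = 0.4, shape = 16) +
    ggplot2::labs(x = "x (um)", colour = NULL,
                  y = if (plane == "xy") "depth (um)" else "z (um)") +
    ggplot2::theme_minimal()
  if (plane == "xy") p <- p + ggplot2::scale_y_reverse()
  p
}
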