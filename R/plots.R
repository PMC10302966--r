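# ---- ggplot2 display methods ------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   scale_fill_viridis_c coord_equal labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a temperature field snapshot
#'
#' @param object A [simulate_conduction()] result.
#' @param time_s Snapshot time to display (nearest recorded snapshot;
#'   default: the last).
#' @param ... Unused.
#' @return A ggplot object (cross-section raster, degC).
#' @export
autoplot.temperature_field <- function(object, time_s = NULL, ...) {
  s <- if (is.null(time_s)) length(object$times) else
    which.min(abs(object$times - time_s))
  M <- object$data[, , s]
  df <- tidyr::expand_grid(x_mm = object$map$x_centers,
                           z_mm = object$map$z_centers)
  df$T_C <- as.vector(M)
  df <- df[!is.na(df$T_C), ]
  ggplot(df, aes(x = .data$x_mm, y = .data$z_mm, fill = .data$T_C)) +
    geom_raster() +
    scale_fill_viridis_c(option = "inferno", name = "T (°C)") +
    coord_equal() +
    labs(title = sprintf("t = %.2f s", object$times[s]),
         x = "x (mm)", y = "z (mm)") +
    theme_minimal()
}

#' Plot probe temperature traces
#'
#' @param object A [probe_temperature()] result.
#' @param ... Unused.
#' @return A ggplot object of temperature versus time per probe.
#' @export
autoplot.probe_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$T_C,
                     colour = .data$probe_id)) +
    geom_line() +
    labs(x = "time (s)", y = "temperature (°C)", colour = "probe") +
    theme_minimal()
}

#' Plot per-grade accuracies of a confusion report
#'
#' @param object A [confusion_report()].
#' @param ... Unused.
#' @return A ggplot bar chart of per-grade accuracy.
#' @export
autoplot.confusion_report <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$grade, y = .data$accuracy_pct)) +
    geom_col(fill = "steelblue") +
    labs(x = "grade", y = "accuracy (%)",
         title = sprintf("overall %.2f%%", overall_accuracy(object))) +
    theme_minimal()
}

#' Display a thermal video frame
#'
#' @param frame `H x W x 3` array with 8-bit channels.
#' @return A ggplot raster of the frame.
#' @export
plot_thermal_frame <- function(frame) {
  stopifnot(length(dim(frame)) == 3)
  d <- dim(frame)
  df <- tidyr::expand_grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$col <- grDevices::rgb(frame[, , 1], frame[, , 2], frame[, , 3],
                           maxColorValue = 255)
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_raster(fill = df$col) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
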