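#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for analysis results
#'
#' `autoplot()` methods returning ggplot objects: voltage traces as time
#' series, spectra as dB-vs-frequency lines, cross-correlations as
#' lag-vs-coefficient lines, PCA decompositions as score scatters, and
#' gate-state matrices as the red/black activation heatmap (red = logic
#' HIGH, black = LOW).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name protact-plots
NULL

#' @rdname protact-plots
#' @exportS3Method ggplot2::autoplot
autoplot.voltage_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time [s]", y = "voltage [V]", title = trace_label(object)
    )
}

#' @rdname protact-plots
#' @exportS3Method ggplot2::autoplot
autoplot.trace_spectrum <- function(object, ...) {
  ggplot2::ggplot(
    object$bins,
    ggplot2::aes(x = .data$freq, y = .data$power_db)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::annotate(
      "point",
      x = object$dominant_mode,
      y = max(object$bins$power_db),
      shape = 1, size = 4, colour = "red"
    ) +
    ggplot2::labs(x = "frequency [Hz]", y = "magnitude [dB]")
}

#' @rdname protact-plots
#' @exportS3Method ggplot2::autoplot
autoplot.xcorr_result <- function(object, ...) {
  ggplot2::ggplot(
    object$lags,
    ggplot2::aes(x = .data$lag, y = .data$coeff)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(
      xintercept = object$argmax_lag, linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(x = "lag [samples]", y = "correlation")
}

#' @rdname protact-plots
#' @exportS3Method ggplot2::autoplot
autoplot.trace_pca <- function(object, ...) {
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  ) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", 100 * object$var_fraction[1]),
      y = sprintf("PC2 (%.2f%%)", 100 * object$var_fraction[2])
    )
}

#' @rdname protact-plots
#' @exportS3Method ggplot2::autoplot
autoplot.gate_state_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("step", gate_columns)],
    cols = -"step", names_to = "gate", values_to = "state"
  )
  long$gate <- factor(long$gate, levels = rev(gate_columns))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$step, y = .data$gate, fill = factor(.data$state))
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(`0` = "black", `1` = "red"), name = "state"
    ) +
    ggplot2::labs(x = "time step", y = NULL)
}

#' @rdname protact-plots
#' @exportS3Method ggplot2::autoplot
autoplot.micrograph <- function(object, ...) {
  df <- expand.grid(
    row = seq_len(nrow(object$pixels)),
    col = seq_len(ncol(object$pixels))
  )
  df$intensity <- as.vector(object$pixels)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname protact-plots
#' @param type For `morphometry_summary`: plot the length `"histogram"`.
#' @exportS3Method ggplot2::autoplot
autoplot.morphometry_summary <- function(object, type = "histogram", ...) {
  ggplot2::ggplot(
    object$histogram,
    ggplot2::aes(x = .data$bin_mid, y = .data$count)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "major-axis length [nm]", y = "count")
}

#' @importFrom rlang .data
NULL
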