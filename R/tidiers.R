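#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for analysis results
#'
#' broom-style `tidy()` (one row per element) and `glance()` (one-row
#' summary) methods for the package's result objects.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name protact-tidiers
NULL

#' @rdname protact-tidiers
#' @exportS3Method generics::tidy
tidy.trace_spectrum <- function(x, ...) x$bins

#' @rdname protact-tidiers
#' @exportS3Method generics::glance
glance.trace_spectrum <- function(x, ...) {
  tibble::tibble(
    mean_db = x$mean_db, sd_db = x$sd_db,
    dominant_mode = x$dominant_mode, n = x$n
  )
}

#' @rdname protact-tidiers
#' @exportS3Method generics::tidy
tidy.xcorr_result <- function(x, ...) x$lags

#' @rdname protact-tidiers
#' @exportS3Method generics::glance
glance.xcorr_result <- function(x, ...) {
  tibble::tibble(
    max_coeff = x$max_coeff, argmax_lag = x$argmax_lag, n = x$n
  )
}

#' @rdname protact-tidiers
#' @exportS3Method generics::tidy
tidy.trace_pca <- function(x, ...) {
  tibble::tibble(
    component = names(x$var_fraction),
    var_fraction = as.numeric(x$var_fraction)
  )
}

#' @rdname protact-tidiers
#' @exportS3Method generics::glance
glance.trace_pca <- function(x, ...) {
  tibble::tibble(
    pc1_fraction = x$var_fraction[[1]],
    pc2_fraction = x$var_fraction[[2]],
    standardize = x$standardize,
    degenerate = x$degenerate,
    n = x$n
  )
}

#' @rdname protact-tidiers
#' @exportS3Method generics::tidy
tidy.lyapunov_estimate <- function(x, ...) {
  tibble::tibble(
    lambda_per_step = x$lambda_per_step, n_pairs = x$n_pairs
  )
}

#' @rdname protact-tidiers
#' @exportS3Method generics::glance
glance.lyapunov_estimate <- function(x, ...) {
  tibble::tibble(
    lambda_per_step = x$lambda_per_step,
    n_pairs = x$n_pairs,
    pairing = x$config$pairing,
    smooth = x$config$smooth
  )
}

#' @rdname protact-tidiers
#' @exportS3Method generics::tidy
tidy.segmentation_result <- function(x, ...) x$components

#' @rdname protact-tidiers
#' @exportS3Method generics::glance
glance.segmentation_result <- function(x, ...) {
  s <- morphometry_summary(x)
  s$stats
}

#' @rdname protact-tidiers
#' @exportS3Method generics::tidy
tidy.analysis_report <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::bind_rows(
      dplyr::mutate(x$input_stats, channel = "input"),
      dplyr::mutate(x$output_stats, channel = "output")
    ),
    cols = -"channel", names_to = "metric", values_to = "value"
  )
}

#' @rdname protact-tidiers
#' @exportS3Method generics::glance
glance.analysis_report <- function(x, ...) {
  tibble::tibble(
    system = x$provenance$system,
    seed = x$provenance$seed,
    attenuation = x$output_stats$sd / x$input_stats$sd,
    xcorr_max = x$xcorr$max_coeff,
    pc1_fraction = x$pca$var_fraction[[1]],
    lambda_input = if (is.null(x$lyapunov_input)) NA_real_ else
      x$lyapunov_input$lambda_per_step,
    lambda_output = if (is.null(x$lyapunov_output)) NA_real_ else
      x$lyapunov_output$lambda_per_step
  )
}
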