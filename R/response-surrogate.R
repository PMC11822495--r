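#' Surrogate transfer parameters
#'
#' Parameterises the phenomenological stand-in for the proteinoid-actin
#' composite's input-to-output transformation. The surrogate encodes the
#' transfer signatures observed on the real composite - strong amplitude
#' suppression (5-30 fold), a bounded output range, approximate preservation
#' of spectral structure with an optional dominant-mode shift, and
#' small-amplitude additive noise - without claiming any mechanistic model
#' of the material.
#'
#' @param gain Dimensionless attenuation factor (> 0); the composite
#'   operates around 0.03-0.2 depending on the drive.
#' @param offset Output offset in volts.
#' @param v_min,v_max Output clamp bounds in volts (defaults unbounded).
#' @param lp_cutoff Low-pass cutoff in Hz for the zero-phase moving-average
#'   smoothing kernel; `Inf` disables smoothing. Must be below the Nyquist
#'   frequency of the trace it is applied to.
#' @param freq_shift Dominant-mode shift in Hz applied by resampling the
#'   time axis; 0 (default) disables it. Negative values reproduce the
#'   composite's ~0.05 Hz downward shift, positive values its
#'   frequency-multiplying regime.
#' @param noise_sd Standard deviation of additive Gaussian noise in volts.
#' @param seed Integer seed for the noise draw.
#' @return A list of class `surrogate_params`.
#' @export
surrogate_params <- function(gain = 0.05, offset = 0, v_min = -Inf,
                             v_max = Inf, lp_cutoff = Inf, freq_shift = 0,
                             noise_sd = 0, seed = NULL) {
  if (gain <= 0) stop("`gain` must be positive", call. = FALSE)
  if (v_min >= v_max) stop("`v_min` must be below `v_max`", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(
    list(
      gain = gain, offset = offset, v_min = v_min, v_max = v_max,
      lp_cutoff = lp_cutoff, freq_shift = freq_shift,
      noise_sd = noise_sd, seed = seed
    ),
    class = "surrogate_params"
  )
}

#' Built-in surrogate presets
#'
#' Loads one of the per-system surrogate parameter presets shipped under
#' `inst/extdata/presets/`. Each preset was chosen once so that the
#' surrogate output of the corresponding default drive approximates the
#' output voltage statistics reported for the composite under that drive;
#' they are presets for synthetic experimentation, never ground truth.
#'
#' @param system One of `"logistic"`, `"baker"`, `"lorenz"`, `"rossler"`,
#'   `"fhn"`.
#' @param seed Optional seed stored into the returned parameters.
#' @return A [surrogate_params()] object.
#' @export
surrogate_preset <- function(system = c("logistic", "baker", "lorenz",
                                        "rossler", "fhn"),
                             seed = NULL) {
  system <- match.arg(system)
  path <- system.file("extdata", "presets", paste0(system, ".json"),
    package = "protact"
  )
  if (!nzchar(path)) stop("preset not found for ", system, call. = FALSE)
  p <- jsonlite::fromJSON(path)
  surrogate_params(
    gain = p$gain, offset = p$offset,
    v_min = if (is.null(p$v_min)) -Inf else p$v_min,
    v_max = if (is.null(p$v_max)) Inf else p$v_max,
    lp_cutoff = if (is.null(p$lp_cutoff)) Inf else p$lp_cutoff,
    freq_shift = if (is.null(p$freq_shift)) 0 else p$freq_shift,
    noise_sd = if (is.null(p$noise_sd)) 0 else p$noise_sd,
    seed = seed
  )
}

# symmetric moving-average low-pass; window derived from cutoff and dt
lowpass_ma <- function(v, lp_cutoff, dt) {
  if (!is.finite(lp_cutoff)) {
    return(v)
  }
  nyquist <- 1 / (2 * dt)
  if (lp_cutoff >= nyquist) {
    stop(
      "`lp_cutoff` (", lp_cutoff, " Hz) must be below the Nyquist frequency (",
      nyquist, " Hz)",
      call. = FALSE
    )
  }
  if (lp_cutoff <= 0) stop("`lp_cutoff` must be positive", call. = FALSE)
  w <- max(1L, round(1 / (lp_cutoff * dt)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) {
    return(v)
  }
  half <- (w - 1L) %/% 2L
  # reflect-pad so edges keep the trace length and the kernel stays symmetric
  padded <- c(rev(v[2:(half + 1)]), v, rev(v[(length(v) - half):(length(v) - 1)]))
  as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[
    (half + 1):(half + length(v))
  ]
}

#' Apply the composite-response surrogate
#'
#' Transforms an input drive trace the way the proteinoid-actin composite
#' transforms applied voltages: zero-phase low-pass smoothing, gain
#' attenuation and offset, clamping to a bounded output range, an optional
#' dominant-mode frequency shift, and seeded additive Gaussian noise:
#' \deqn{y = \mathrm{clamp}(g \cdot \mathrm{LP}(x) + b,\; v_{min},
#'   v_{max}) + \varepsilon}
#' With `noise_sd = 0` the map is deterministic; output length and sampling
#' interval equal the input's.
#'
#' @param trace Input [voltage_trace()].
#' @param params A [surrogate_params()] object.
#' @return A [voltage_trace()] of the same length and `dt` as the input.
#' @examples
#' drv <- generate_logistic(n_iter = 1000, seed = 1)
#' out <- apply_surrogate(drv, surrogate_params(gain = 0.05, noise_sd = 0))
#' sd(out$voltage) / sd(drv$voltage)
#' @export
apply_surrogate <- function(trace, params = surrogate_params()) {
  trace <- check_trace(trace)
  stopifnot(inherits(params, "surrogate_params"))
  dt <- trace_dt(trace)
  v <- lowpass_ma(trace$voltage, params$lp_cutoff, dt)
  v <- params$gain * v + params$offset
  v <- pmin(pmax(v, params$v_min), params$v_max)
  if (params$freq_shift != 0) {
    v <- shift_dominant_mode(v, dt, params$freq_shift)
  }
  if (params$noise_sd > 0) {
    noise <- if (!is.null(params$seed)) {
      withr_seed(params$seed, stats::rnorm(length(v), 0, params$noise_sd))
    } else {
      stats::rnorm(length(v), 0, params$noise_sd)
    }
    v <- v + noise
  }
  out <- new_voltage_trace(trace$time, v,
    dt = dt,
    label = paste0(trace_label(trace), " -> surrogate")
  )
  attr(out, "spec") <- unclass(params)
  out
}

# shift the dominant (peak-rate) frequency by delta_f via time-axis
# resampling; a crude spectral transposition, documented as such
shift_dominant_mode <- function(v, dt, delta_f) {
  n <- length(v)
  tr <- new_voltage_trace((seq_len(n) - 1) * dt, v, dt = dt)
  f0 <- peaks_per_second(tr)
  if (f0 <= 0 || f0 + delta_f <= 0) {
    return(v)
  }
  r <- (f0 + delta_f) / f0
  src <- (seq_len(n) - 1) * r
  src <- pmin(src, n - 1)
  stats::approx(x = 0:(n - 1), y = v, xout = src, rule = 2)$y
}

#' Sigmoid spiking coupling
#'
#' Applies the synaptic-like pointwise logistic transform that couples an
#' input channel to the composite's output channel:
#' \deqn{V_{out}(t) = \frac{1}{1 + e^{-m (V_{in}(t) - c)}}}
#' Sub-threshold inputs map to proportional small outputs; crossing the
#' midpoint threshold `c` (0.5 V by default) drives the output to spike.
#' Large slopes `m` approach a step at `c`, imitating all-or-none firing.
#' The transform is monotone nondecreasing in the input.
#'
#' @param trace Input [voltage_trace()].
#' @param midpoint_c Sigmoid midpoint in volts (half-maximum point).
#' @param slope_m Sigmoid steepness (> 0), dimensionless.
#' @return A [voltage_trace()] with voltages in (0, 1).
#' @export
apply_sigmoid_coupling <- function(trace, midpoint_c = 0.5, slope_m = 10) {
  trace <- check_trace(trace)
  if (slope_m <= 0) stop("`slope_m` must be positive", call. = FALSE)
  v <- 1 / (1 + exp(-slope_m * (trace$voltage - midpoint_c)))
  new_voltage_trace(trace$time, v,
    dt = trace_dt(trace),
    label = paste0(trace_label(trace), " -> sigmoid")
  )
}

#' Recover surrogate parameters from a paired input/output
#'
#' One-shot closed-form estimation of the surrogate transfer from a paired
#' drive and response: the clamp bounds are the output extrema (exact when
#' the clamp is active), the gain is the covariance slope
#' \eqn{\hat g = \mathrm{cov}(y, x) / \mathrm{var}(x)} over the samples not
#' sitting on the clamp (unbiased under additive output noise, exact when
#' noise is absent), and the offset is the mean residual
#' \eqn{\hat b = \overline{y - \hat g x}}. No iterative fitting is
#' performed, and the low-pass stage is not deconvolved: when smoothing was
#' active the recovered gain is the effective pass-band gain.
#'
#' @param input,output Paired [voltage_trace()]s of equal length.
#' @return A tibble with columns `gain`, `offset`, `v_min`, `v_max`,
#'   `n_clamped` (samples sitting on either recovered bound).
#' @examples
#' drv <- generate_logistic(n_iter = 2000, seed = 1)
#' out <- apply_surrogate(drv, surrogate_params(gain = 0.04))
#' recover_surrogate_params(drv, out)
#' @export
recover_surrogate_params <- function(input, output) {
  input <- check_trace(input)
  output <- check_trace(output)
  if (nrow(input) != nrow(output)) {
    stop("paired traces must have equal length", call. = FALSE)
  }
  x <- input$voltage
  y <- output$voltage
  if (stats::var(x) == 0) {
    stop("zero input variance: gain is not identifiable", call. = FALSE)
  }
  v_min <- min(y)
  v_max <- max(y)
  on_min <- y == v_min
  on_max <- y == v_max
  clamped <- (sum(on_min) > 1 & on_min) | (sum(on_max) > 1 & on_max)
  keep <- !clamped
  if (sum(keep) < 3) keep <- rep(TRUE, length(y))
  gain <- stats::cov(y[keep], x[keep]) / stats::var(x[keep])
  offset <- mean(y[keep] - gain * x[keep])
  tibble::tibble(
    gain = gain, offset = offset, v_min = v_min, v_max = v_max,
    n_clamped = sum(clamped)
  )
}
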