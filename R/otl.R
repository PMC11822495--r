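#' Binary bit streams
#'
#' A bit stream is the digital counterpart of a voltage trace: a tibble
#' with columns `step` and `bit` (0/1), carrying the sampling interval and
#' an origin label ("V1_in", "OTL", ...) as attributes.
#'
#' @param bits Integer/logical vector of 0s and 1s.
#' @param dt Sampling interval in seconds.
#' @param origin Free-text channel label.
#' @return A tibble of class `bit_stream`.
#' @export
bit_stream <- function(bits, dt = 1, origin = "") {
  bits <- as.integer(bits)
  if (length(bits) > 0 && !all(bits %in% c(0L, 1L))) {
    stop("bits must be 0 or 1", call. = FALSE)
  }
  tibble::new_tibble(
    list(step = seq_along(bits), bit = bits),
    nrow = length(bits),
    dt = dt, origin = origin,
    class = "bit_stream"
  )
}

#' @rdname bit_stream
#' @param x Object to test.
#' @export
is_bit_stream <- function(x) inherits(x, "bit_stream")

stream_bits <- function(x) {
  if (is_bit_stream(x) || (is.data.frame(x) && "bit" %in% names(x))) {
    as.integer(x$bit)
  } else {
    as.integer(x)
  }
}

stream_dt <- function(x) {
  dt <- attr(x, "dt")
  if (is.null(dt)) 1 else dt
}

check_aligned <- function(a, b) {
  na <- if (is.data.frame(a)) nrow(a) else length(a)
  nb <- if (is.data.frame(b)) nrow(b) else length(b)
  if (na != nb) stop("bit streams must have equal length", call. = FALSE)
  invisible(NULL)
}

#' Oscillatory thresholding of a voltage trace
#'
#' Converts analog voltage oscillations into logic bits: a sample is HIGH
#' (1) when the voltage strictly exceeds the discrimination threshold
#' `theta` *and* belongs to a suprathreshold run lasting at least `tau_min`
#' seconds. The duration constraint models the minimum time the composite
#' needs for a stable conformational change, filtering out transient
#' fluctuations; with `tau_min = 0` the operation reduces to a plain
#' comparison. Voltages exactly equal to `theta` map to 0 (the threshold
#' must be surpassed). Increasing `tau_min` can only turn 1s into 0s,
#' never the reverse.
#'
#' @param trace A [voltage_trace()].
#' @param theta Discrimination threshold in volts. The default 0.5 V is the
#'   explicitly stated operating threshold; see [otl_theta_presets()] for
#'   the alternative derived from resting-potential statistics.
#' @param tau_min Minimum suprathreshold duration in seconds (default
#'   0.1 s).
#' @return A [bit_stream()] with one bit per sample and the trace's `dt`.
#' @examples
#' t <- seq(0, 1, 0.01)
#' threshold_bits(voltage_trace(t, rep(0.6, length(t))), theta = 0.5)
#' @export
threshold_bits <- function(trace, theta = 0.5, tau_min = 0.1) {
  trace <- check_trace(trace)
  if (tau_min < 0) stop("`tau_min` must be non-negative", call. = FALSE)
  dt <- trace_dt(trace)
  raw <- trace$voltage > theta
  if (tau_min > 0 && any(raw)) {
    r <- rle(raw)
    keep <- r$values & (r$lengths * dt >= tau_min)
    r$values <- keep
    raw <- inverse.rle(r)
  }
  bit_stream(as.integer(raw), dt = dt, origin = trace_label(trace))
}

#' Preset discrimination thresholds
#'
#' Two thresholds for [threshold_bits()]: `"stated"` is the 0.5 V operating
#' value used throughout the logic experiments; `"derived"` is the resting
#' potential plus two standard deviations (0.0212 + 2 x 0.0176 = 0.0564 V),
#' the statistical derivation quoted for it. The two are mutually
#' inconsistent in the source material, so both ship and `"stated"` is the
#' default elsewhere.
#'
#' @return Named numeric vector of thresholds in volts.
#' @export
otl_theta_presets <- function() {
  c(stated = 0.5, derived = 0.0212 + 2 * 0.0176)
}

#' Boolean gates on bit streams
#'
#' Elementwise OR, AND and NOT over aligned bit streams. In the
#' half-adder scheme the OR gate produces the sum output
#' \eqn{Y = A \lor B} and the AND gate the carry output
#' \eqn{C = A \land B}.
#'
#' @param a,b [bit_stream()]s (or plain 0/1 vectors) of equal length.
#' @return A [bit_stream()].
#' @examples
#' gate_or(c(0, 0, 1, 1), c(0, 1, 0, 1))$bit
#' gate_and(c(0, 0, 1, 1), c(0, 1, 0, 1))$bit
#' @export
gate_or <- function(a, b) {
  check_aligned(a, b)
  bit_stream(as.integer(stream_bits(a) | stream_bits(b)),
    dt = stream_dt(a), origin = "OR"
  )
}

#' @rdname gate_or
#' @export
gate_and <- function(a, b) {
  check_aligned(a, b)
  bit_stream(as.integer(stream_bits(a) & stream_bits(b)),
    dt = stream_dt(a), origin = "AND"
  )
}

#' @rdname gate_or
#' @export
gate_not <- function(a) {
  bit_stream(1L - stream_bits(a), dt = stream_dt(a), origin = "NOT")
}

#' @rdname gate_or
#' @export
gate_xor <- function(a, b) {
  check_aligned(a, b)
  bit_stream(as.integer(xor(stream_bits(a) == 1L, stream_bits(b) == 1L)),
    dt = stream_dt(a), origin = "XOR"
  )
}

#' Half adder on bit streams
#'
#' Composes the sum and carry outputs of a binary half adder from two
#' aligned bit streams. The reference semantics follow the printed gate
#' definitions - sum as OR, carry as AND - under which the (1, 1) input
#' yields sum 1 (a nonstandard half adder). The conventional XOR sum is
#' available with `sum_gate = "xor"`.
#'
#' @inheritParams gate_or
#' @param sum_gate `"or"` (printed semantics, default) or `"xor"`
#'   (conventional).
#' @return A list with [bit_stream()] elements `sum` and `carry`.
#' @examples
#' half_adder(0, 1) # sum 1, carry 0
#' @export
half_adder <- function(a, b, sum_gate = c("or", "xor")) {
  sum_gate <- match.arg(sum_gate)
  s <- if (sum_gate == "or") gate_or(a, b) else gate_xor(a, b)
  list(sum = s, carry = gate_and(a, b))
}

#' Half-adder truth table
#'
#' Evaluates the half adder over all four input combinations.
#'
#' @inheritParams half_adder
#' @return A tibble with columns `a`, `b`, `sum`, `carry`.
#' @export
half_adder_table <- function(sum_gate = c("or", "xor")) {
  sum_gate <- match.arg(sum_gate)
  grid <- tidyr::expand_grid(a = 0:1, b = 0:1)
  out <- half_adder(grid$a, grid$b, sum_gate = sum_gate)
  dplyr::mutate(grid, sum = out$sum$bit, carry = out$carry$bit)
}

#' Oscillatory Threshold Logic pipeline
#'
#' Runs the full OTL transformation over the four recorded channels (two
#' input node voltages `V1_in`, `W1_in` and two output node voltages
#' `V1_out`, `W1_out`): each channel is passed through the oscillatory
#' thresholding function `f()` (threshold `theta`, minimum duration
#' `tau_min`), the output gates are the AND of their duration-constrained
#' bits with the plain suprathreshold comparison (the duration-free bit),
#' and the overall OTL gate is the OR of the two output gates, so a
#' suprathreshold event in either output channel registers a positive OTL
#' result. The input gate columns report `f()` of the input channels.
#'
#' @param v1_in,w1_in,v1_out,w1_out Aligned [voltage_trace()]s.
#' @param theta Discrimination threshold in volts.
#' @param tau_min Minimum suprathreshold duration in seconds.
#' @return A tibble of class `gate_state_matrix` with columns `step`,
#'   `time`, `V1_in`, `W1_in`, `V1_out`, `W1_out`, `OTL` (all bits 0/1).
#' @export
otl_pipeline <- function(v1_in, w1_in, v1_out, w1_out, theta = 0.5,
                         tau_min = 0.1) {
  traces <- lapply(list(v1_in, w1_in, v1_out, w1_out), check_trace)
  ns <- vapply(traces, nrow, integer(1))
  dts <- vapply(traces, trace_dt, numeric(1))
  if (length(unique(ns)) != 1 || max(abs(dts - dts[1])) > 1e-9 * dts[1]) {
    stop("the four traces must be aligned (equal length and dt)",
      call. = FALSE
    )
  }
  f <- lapply(traces, threshold_bits, theta = theta, tau_min = tau_min)
  plain <- lapply(traces, threshold_bits, theta = theta, tau_min = 0)
  gate_in_v <- f[[1]]$bit
  gate_in_w <- f[[2]]$bit
  gate_out_v <- as.integer(f[[3]]$bit & plain[[3]]$bit)
  gate_out_w <- as.integer(f[[4]]$bit & plain[[4]]$bit)
  otl <- as.integer(gate_out_v | gate_out_w)
  dt <- dts[1]
  tibble::new_tibble(
    list(
      step = seq_len(ns[1]),
      time = traces[[1]]$time,
      V1_in = gate_in_v,
      W1_in = gate_in_w,
      V1_out = gate_out_v,
      W1_out = gate_out_w,
      OTL = otl
    ),
    nrow = ns[1],
    dt = dt, theta = theta, tau_min = tau_min,
    class = "gate_state_matrix"
  )
}

gate_columns <- c("V1_in", "W1_in", "V1_out", "W1_out", "OTL")

#' Truth-table report from a gate-state matrix
#'
#' Tabulates the gate states at requested time steps in the layout of the
#' study's truth-table analysis (one row per sampled step, one column per
#' gate).
#'
#' @param matrix A `gate_state_matrix` from [otl_pipeline()].
#' @param steps Integer time steps to sample (1-based). An empty vector
#'   returns an empty table.
#' @return A tibble with columns `step`, `V1_in`, `W1_in`, `V1_out`,
#'   `W1_out`, `OTL`.
#' @export
truth_table_report <- function(matrix, steps = c(1:5, 10, 25, 50, 100, 500,
                                                 1000, 1500, 2000)) {
  stopifnot(inherits(matrix, "gate_state_matrix") ||
    all(gate_columns %in% names(matrix)))
  if (length(steps) == 0) {
    return(tibble::as_tibble(matrix)[0, c("step", gate_columns)])
  }
  if (any(steps < 1 | steps > nrow(matrix))) {
    stop("requested step out of range 1..", nrow(matrix), call. = FALSE)
  }
  tibble::as_tibble(matrix)[steps, c("step", gate_columns)]
}

#' Read and write gate-state matrices as CSV
#'
#' One column per gate plus the step index; round-trips losslessly.
#'
#' @param matrix A `gate_state_matrix`.
#' @param path File path.
#' @return `write_gate_states()` returns `path` invisibly;
#'   `read_gate_states()` returns a `gate_state_matrix`.
#' @export
write_gate_states <- function(matrix, path) {
  df <- as.data.frame(matrix)[, c("step", "time", gate_columns)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gate_states
#' @export
read_gate_states <- function(path) {
  df <- utils::read.csv(path)
  dt <- if (nrow(df) >= 2) df$time[2] - df$time[1] else 1
  tibble::new_tibble(
    df,
    nrow = nrow(df), dt = dt,
    class = "gate_state_matrix"
  )
}
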