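#' Logistic-map voltage drive
#'
#' Iterates the logistic difference equation
#' \eqn{x_{n+1} = \mu x_n (1 - x_n)} and linearly rescales the iterates from
#' the unit interval to a voltage range, producing the quasi-chaotic drive
#' waveform used to stimulate proteinoid-actin networks. At the default
#' growth rate \eqn{\mu = 3.8} the map shows fully developed chaos across
#' the unit interval; at \eqn{\mu = 4} the invariant density spans `[0, 1]`
#' and the analytic Lyapunov exponent is \eqn{\ln 2} per iteration.
#'
#' One iterate is one sample; the playback interval `dt` is configurable
#' (default 0.01 s) so spectral quantities are well defined.
#'
#' @param mu Growth-rate parameter, in (0, 4]. Values above 4 let iterates
#'   escape the unit interval and are rejected.
#' @param x0 Initial value in (0, 1). `NULL` draws uniformly on
#'   (0.01, 0.99) using `seed`, avoiding the absorbing endpoints.
#' @param n_iter Number of iterates (trace length). Default 10,000.
#' @param v_lo,v_hi Output voltage range in volts. Defaults -0.5 and +0.5 V
#'   (the -500..+500 mV drive encoding).
#' @param dt Playback sampling interval in seconds.
#' @param seed Integer seed used when `x0` is drawn randomly.
#' @return A [voltage_trace()] of `n_iter` samples.
#' @examples
#' tr <- generate_logistic(mu = 3.8, n_iter = 500, seed = 1)
#' range(tr$voltage)
#' @export
generate_logistic <- function(mu = 3.8, x0 = NULL, n_iter = 10000,
                              v_lo = -0.5, v_hi = 0.5, dt = 0.01,
                              seed = NULL) {
  if (mu > 4) {
    stop("`mu` > 4 diverges: iterates may leave [0, 1]", call. = FALSE)
  }
  if (mu <= 0) stop("`mu` must be positive", call. = FALSE)
  if (v_lo >= v_hi) stop("`v_lo` must be below `v_hi`", call. = FALSE)
  if (is.null(x0)) {
    if (!is.null(seed)) {
      x0 <- withr_seed(seed, stats::runif(1, 0.01, 0.99))
    } else {
      x0 <- stats::runif(1, 0.01, 0.99)
    }
  }
  if (x0 <= 0 || x0 >= 1) stop("`x0` must lie in (0, 1)", call. = FALSE)
  x <- logistic_orbit(mu, x0, n_iter)
  tr <- new_voltage_trace(
    time = (seq_len(n_iter) - 1) * dt,
    voltage = v_lo + (v_hi - v_lo) * x,
    dt = dt, label = "logistic map"
  )
  attr(tr, "spec") <- list(
    system = "logistic", mu = mu, x0 = x0, n_iter = n_iter,
    v_lo = v_lo, v_hi = v_hi, dt = dt, seed = seed
  )
  tr
}

logistic_orbit <- function(mu, x0, n_iter) {
  x <- numeric(n_iter)
  xi <- x0
  for (i in seq_len(n_iter)) {
    x[i] <- xi
    xi <- mu * xi * (1 - xi)
  }
  x
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

#' Baker-map voltage drive
#'
#' Iterates the standard two-dimensional baker transformation - the
#' stretch-and-fold archetype of mixing chaos - on the unit square and emits
#' one coordinate linearly scaled to a voltage range. With fold parameter
#' \eqn{\alpha}:
#' \deqn{(x, y) \mapsto (x/\alpha,\; \alpha y) \quad x < \alpha}
#' \deqn{(x, y) \mapsto ((x-\alpha)/(1-\alpha),\; \alpha + (1-\alpha) y)
#'   \quad x \ge \alpha}
#'
#' @param alpha Fold parameter in (0, 1); 0.5 is the classic area-halving
#'   map.
#' @param x0,y0 Initial point in the unit square.
#' @param n_iter Number of iterates.
#' @param v_lo,v_hi Output voltage range in volts.
#' @param component Which coordinate to emit, `"x"` or `"y"`.
#' @param dt Playback sampling interval in seconds.
#' @return A [voltage_trace()] of `n_iter` samples, all values within
#'   `[v_lo, v_hi]`.
#' @export
generate_baker <- function(alpha = 0.5, x0 = 0.3, y0 = 0.4, n_iter = 10000,
                           v_lo = -0.5, v_hi = 0.5,
                           component = c("x", "y"), dt = 0.01) {
  component <- match.arg(component)
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (x0 < 0 || x0 > 1 || y0 < 0 || y0 > 1) {
    stop("initial point must lie in the unit square", call. = FALSE)
  }
  if (v_lo >= v_hi) stop("`v_lo` must be below `v_hi`", call. = FALSE)
  pts <- baker_orbit(alpha, x0, y0, n_iter)
  z <- if (component == "x") pts$x else pts$y
  tr <- new_voltage_trace(
    time = (seq_len(n_iter) - 1) * dt,
    voltage = v_lo + (v_hi - v_lo) * z,
    dt = dt, label = "baker map"
  )
  attr(tr, "spec") <- list(
    system = "baker", alpha = alpha, x0 = x0, y0 = y0, n_iter = n_iter,
    v_lo = v_lo, v_hi = v_hi, component = component, dt = dt
  )
  tr
}

baker_orbit <- function(alpha, x0, y0, n_iter) {
  x <- numeric(n_iter)
  y <- numeric(n_iter)
  xi <- x0
  yi <- y0
  for (i in seq_len(n_iter)) {
    x[i] <- xi
    y[i] <- yi
    if (xi < alpha) {
      xi2 <- xi / alpha
      yi <- alpha * yi
    } else {
      xi2 <- (xi - alpha) / (1 - alpha)
      yi <- alpha + (1 - alpha) * yi
    }
    xi <- xi2
  }
  list(x = x, y = y)
}

# fixed-step RK4 integration via deSolve, with a non-finite state check
integrate_rk4 <- function(deriv, y0, dt, duration, parms) {
  times <- seq(0, duration, by = dt)
  out <- deSolve::ode(y0, times, deriv, parms, method = "rk4")
  bad <- which(!stats::complete.cases(out) | apply(!is.finite(out), 1, any))
  if (length(bad) > 0) {
    stop(
      "non-finite state during integration at step ", bad[1] - 1,
      call. = FALSE
    )
  }
  out
}

#' Lorenz-attractor voltage drive
#'
#' Integrates the Lorenz system
#' \deqn{\dot x = \sigma (y - x), \quad \dot y = x(\rho - z) - y, \quad
#'   \dot z = x y - \beta z}
#' with a classic fixed-step fourth-order Runge-Kutta solver and returns the
#' selected component scaled to volts. Defaults are the chaotic-attractor
#' parameters \eqn{\sigma = 10}, \eqn{\rho = 28}, \eqn{\beta = 8/3}, initial
#' state (0, 1, 1.05), step 0.01 s over 100 s, giving a 10,001-sample trace.
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @param y0 Numeric length-3 initial state (x, y, z).
#' @param dt Integration step in seconds.
#' @param duration Total integration time in seconds.
#' @param scale Volts per state-unit applied to the emitted component.
#' @param component Which state variable to emit.
#' @return A [voltage_trace()] of `floor(duration/dt) + 1` samples.
#' @export
generate_lorenz <- function(sigma = 10, rho = 28, beta = 8 / 3,
                            y0 = c(0, 1, 1.05), dt = 0.01, duration = 100,
                            scale = 1, component = c("x", "y", "z")) {
  component <- match.arg(component)
  stopifnot(dt > 0, duration > dt, scale > 0, length(y0) == 3)
  deriv <- function(t, state, p) {
    x <- state[1]
    y <- state[2]
    z <- state[3]
    list(c(
      p$sigma * (y - x),
      x * (p$rho - z) - y,
      x * y - p$beta * z
    ))
  }
  out <- integrate_rk4(deriv, unname(y0), dt, duration,
    parms = list(sigma = sigma, rho = rho, beta = beta)
  )
  k <- match(component, c("x", "y", "z")) + 1
  tr <- new_voltage_trace(out[, 1], out[, k] * scale,
    dt = dt, label = "lorenz attractor"
  )
  attr(tr, "spec") <- list(
    system = "lorenz", sigma = sigma, rho = rho, beta = beta, y0 = y0,
    dt = dt, duration = duration, scale = scale, component = component
  )
  tr
}

#' Rossler-attractor voltage drive
#'
#' Integrates the Rossler system
#' \deqn{\dot x = -y - z, \quad \dot y = x + a y, \quad
#'   \dot z = b + z (x - c)}
#' by fixed-step RK4 and returns the selected component scaled to volts.
#' Defaults \eqn{a = b = 0.2}, \eqn{c = 5.7} yield the chaotic attractor
#' with continuous broadband oscillations.
#'
#' @param a,b,c Rossler parameters.
#' @inheritParams generate_lorenz
#' @return A [voltage_trace()].
#' @export
generate_rossler <- function(a = 0.2, b = 0.2, c = 5.7, y0 = c(1, 1, 1),
                             dt = 0.01, duration = 100, scale = 1,
                             component = c("x", "y", "z")) {
  component <- match.arg(component)
  stopifnot(dt > 0, duration > dt, scale > 0, length(y0) == 3)
  deriv <- function(t, state, p) {
    x <- state[1]
    y <- state[2]
    z <- state[3]
    list(c(
      -y - z,
      x + p$a * y,
      p$b + z * (x - p$c)
    ))
  }
  out <- integrate_rk4(deriv, unname(y0), dt, duration,
    parms = list(a = a, b = b, c = c)
  )
  k <- match(component, c("x", "y", "z")) + 1
  tr <- new_voltage_trace(out[, 1], out[, k] * scale,
    dt = dt, label = "rossler attractor"
  )
  attr(tr, "spec") <- list(
    system = "rossler", a = a, b = b, c = c, y0 = y0,
    dt = dt, duration = duration, scale = scale, component = component
  )
  tr
}

#' FitzHugh-Nagumo voltage drive
#'
#' Integrates a two-variable FitzHugh-Nagumo excitability model
#' \deqn{\dot v = v (v - a)(1 - v) / \gamma - w + c, \qquad
#'   \dot w = \epsilon (v + a - \gamma w)}
#' by fixed-step RK4. `v` is the fast activation variable, `w` the slow
#' recovery variable; `a` sets the excitation threshold, \eqn{\epsilon} the
#' recovery time scale, and \eqn{\gamma} both the recovery leak and the
#' excitation gain \eqn{1/\gamma} of the cubic. With the defaults
#' `a = 0.1`, `epsilon = 0.1`, `gamma = 0.1` and a start at rest (0, 0), the
#' constant drive `c` selects the regime: at `c = 1` the trajectory settles
#' to a quiescent fixed point, while at `c = 2` it sustains a stable
#' relaxation limit cycle, mimicking the transition from resting to
#' repetitive neuronal spiking above a critical input current.
#'
#' @param a Excitation threshold (dimensionless).
#' @param c Constant input drive.
#' @param epsilon Recovery rate.
#' @param gamma Recovery leak; also sets the cubic gain `1/gamma`.
#' @param v0,w0 Initial state.
#' @inheritParams generate_lorenz
#' @param component `"v"` or `"w"` returns that variable as a
#'   [voltage_trace()]; `"both"` returns a tibble with columns `time`, `v`,
#'   `w` (volts, after scaling).
#' @return A [voltage_trace()] or a tibble, per `component`.
#' @examples
#' quiet <- generate_fhn(c = 1, duration = 200)
#' spiking <- generate_fhn(c = 2, duration = 200)
#' @export
generate_fhn <- function(a = 0.1, c = 1, epsilon = 0.1, gamma = 0.1,
                         v0 = 0, w0 = 0, dt = 0.01, duration = 100,
                         scale = 1, component = c("v", "w", "both")) {
  component <- match.arg(component)
  stopifnot(dt > 0, duration > dt, scale > 0, gamma > 0)
  deriv <- function(t, state, p) {
    v <- state[1]
    w <- state[2]
    list(c(
      v * (v - p$a) * (1 - v) / p$gamma - w + p$c,
      p$eps * (v + p$a - p$gamma * w)
    ))
  }
  out <- integrate_rk4(deriv, c(v0, w0), dt, duration,
    parms = list(a = a, c = c, eps = epsilon, gamma = gamma)
  )
  spec <- list(
    system = "fhn", a = a, c = c, epsilon = epsilon, gamma = gamma,
    v0 = v0, w0 = w0, dt = dt, duration = duration, scale = scale
  )
  if (component == "both") {
    tibble::tibble(
      time = out[, 1],
      v = out[, 2] * scale,
      w = out[, 3] * scale
    )
  } else {
    k <- if (component == "v") 2 else 3
    tr <- new_voltage_trace(out[, 1], out[, k] * scale,
      dt = dt, label = paste0("fitzhugh-nagumo ", component)
    )
    attr(tr, "spec") <- c(spec, list(component = component))
    tr
  }
}

#' Seeded binary pulse-train drive
#'
#' Draws a seeded uniform random bit string and encodes it as a voltage
#' pulse train: each 1-bit holds the channel at `v_high` (+500 mV by
#' default) for `pulse_width` seconds, each 0-bit holds it at `v_low`
#' (-500 mV). The trace is sampled at `bit_dt` resolution (1 ms default),
#' so each bit spans `pulse_width / bit_dt` samples. Identical seeds give
#' byte-identical traces.
#'
#' @param n_bits Number of bits to draw.
#' @param bit_dt Sampling resolution in seconds (default 1 ms).
#' @param pulse_width Duration each bit holds its level, in seconds
#'   (default 100 ms). Must be at least `bit_dt`.
#' @param v_high,v_low Encoding levels in volts.
#' @param seed Integer seed; mandatory so runs are reproducible.
#' @param bits Optional explicit 0/1 vector overriding the random draw.
#' @return A list with elements `bits` (a [bit_stream()]) and `trace`
#'   (a [voltage_trace()]).
#' @export
generate_pulse_train <- function(n_bits = 100, bit_dt = 0.001,
                                 pulse_width = 0.1, v_high = 0.5,
                                 v_low = -0.5, seed = 1, bits = NULL) {
  if (pulse_width < bit_dt) {
    stop("`pulse_width` must be at least `bit_dt`", call. = FALSE)
  }
  if (v_low >= v_high) stop("`v_low` must be below `v_high`", call. = FALSE)
  if (is.null(bits)) {
    bits <- withr_seed(seed, as.integer(stats::runif(n_bits) >= 0.5))
  } else {
    bits <- as.integer(bits)
    if (!all(bits %in% c(0L, 1L))) stop("`bits` must be 0/1", call. = FALSE)
    n_bits <- length(bits)
  }
  per_bit <- round(pulse_width / bit_dt)
  level <- ifelse(bits == 1L, v_high, v_low)
  v <- rep(level, each = per_bit)
  tr <- new_voltage_trace(
    time = (seq_along(v) - 1) * bit_dt,
    voltage = v,
    dt = bit_dt, label = "binary pulse train"
  )
  attr(tr, "spec") <- list(
    system = "bits", n_bits = n_bits, bit_dt = bit_dt,
    pulse_width = pulse_width, v_high = v_high, v_low = v_low, seed = seed
  )
  list(
    bits = bit_stream(bits, dt = pulse_width, origin = "pulse train"),
    trace = tr
  )
}
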