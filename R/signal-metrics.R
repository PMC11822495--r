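#' Peak-rate dominant frequency
#'
#' Estimates the "peaks per second" frequency of a trace: the number of
#' prominence-filtered local maxima divided by the total duration. A local
#' maximum counts only when its topographic prominence (height above the
#' highest saddle connecting it to higher terrain) exceeds
#' `prominence_factor` times the standard deviation of the linearly
#' detrended trace, which makes the count robust to recording noise while
#' reducing to plain cycle counting for clean periodic signals.
#'
#' @param trace A [voltage_trace()] with at least 3 samples.
#' @param prominence_factor Multiple of the detrended standard deviation a
#'   peak's prominence must exceed. Default 0.5.
#' @return Frequency in Hz; 0 for zero-variance or monotone traces.
#' @examples
#' t <- seq(0, 10, by = 0.001)
#' peaks_per_second(voltage_trace(t, sin(2 * pi * 3 * t)))
#' @export
peaks_per_second <- function(trace, prominence_factor = 0.5) {
  trace <- check_trace(trace)
  v <- trace$voltage
  n <- length(v)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(v) == 0) {
    return(0)
  }
  detr <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), v))
  thresh <- prominence_factor * stats::sd(detr)
  peaks <- find_peaks(v, min_prominence = thresh)
  length(peaks) / trace_duration(trace)
}

# indices of local maxima with topographic prominence >= min_prominence;
# plateaus count once (at their first sample)
find_peaks <- function(v, min_prominence = 0) {
  n <- length(v)
  if (n < 3) {
    return(integer(0))
  }
  d <- diff(v)
  # rising-then-falling across possible plateaus
  sgn <- sign(d)
  run <- sgn[sgn != 0]
  pos <- which(sgn != 0)
  if (length(run) < 2) {
    return(integer(0))
  }
  cand <- pos[which(run[-length(run)] > 0 & run[-1] < 0) + 1]
  if (length(cand) == 0) {
    return(integer(0))
  }
  keep <- vapply(cand, function(p) {
    peak_prominence(v, p) >= min_prominence
  }, logical(1))
  cand[keep]
}

peak_prominence <- function(v, p) {
  h <- v[p]
  left_min <- h
  i <- p - 1L
  while (i >= 1L && v[i] <= h) {
    if (v[i] < left_min) left_min <- v[i]
    i <- i - 1L
  }
  if (i < 1L) left_min <- min(v[1:p])
  right_min <- h
  n <- length(v)
  i <- p + 1L
  while (i <= n && v[i] <= h) {
    if (v[i] < right_min) right_min <- v[i]
    i <- i + 1L
  }
  if (i > n) right_min <- min(v[p:n])
  h - max(left_min, right_min)
}

#' Summary statistics of a voltage trace
#'
#' Descriptive statistics in the layout of the study's input/output tables:
#' mean, standard deviation, median, maximum, minimum (volts), the
#' peak-rate dominant frequency (Hz) and the sample count.
#'
#' @inheritParams peaks_per_second
#' @return A one-row tibble with columns `mean`, `sd`, `median`, `max`,
#'   `min`, `dominant_freq`, `n`.
#' @examples
#' trace_stats(generate_logistic(n_iter = 1000, seed = 1))
#' @export
trace_stats <- function(trace, prominence_factor = 0.5) {
  trace <- check_trace(trace)
  v <- trace$voltage
  if (length(v) < 2) stop("need at least 2 samples", call. = FALSE)
  tibble::tibble(
    mean = mean(v),
    sd = stats::sd(v),
    median = stats::median(v),
    max = max(v),
    min = min(v),
    dominant_freq = if (length(v) >= 3) {
      peaks_per_second(trace, prominence_factor)
    } else {
      NA_real_
    },
    n = length(v)
  )
}

#' Magnitude spectrum in decibels
#'
#' Computes the one-sided magnitude spectrum of the mean-retained signal as
#' \eqn{20 \log_{10}(|\mathrm{FFT}(v)| / n)}, floored at `floor_db`. The
#' mean is deliberately kept so a DC-dominated trace reports its dominant
#' mode at 0 Hz, matching how the study's spectra are read. `mean_db` and
#' `sd_db` summarise the positive-frequency bins; the dominant mode is the
#' frequency of the largest bin including the zero-frequency bin.
#'
#' @param trace A [voltage_trace()].
#' @param floor_db Lower flooring level in dB (default -200) keeping
#'   log-zero bins finite.
#' @return An object of class `trace_spectrum`: a list with a `bins` tibble
#'   (`freq` in Hz, `power_db`), scalars `mean_db`, `sd_db`,
#'   `dominant_mode` (Hz), and `n`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
trace_spectrum <- function(trace, floor_db = -200) {
  trace <- check_trace(trace)
  v <- trace$voltage
  n <- length(v)
  dt <- trace_dt(trace)
  mag <- Mod(stats::fft(v)) / n
  nf <- floor(n / 2) + 1L
  freq <- (seq_len(nf) - 1) / (n * dt)
  power_db <- pmax(20 * log10(mag[seq_len(nf)]), floor_db)
  pos <- power_db[-1]
  structure(
    list(
      bins = tibble::tibble(freq = freq, power_db = power_db),
      mean_db = mean(pos),
      sd_db = stats::sd(pos),
      dominant_mode = freq[which.max(power_db)],
      floor_db = floor_db,
      n = n
    ),
    class = "trace_spectrum"
  )
}

#' @export
print.trace_spectrum <- function(x, ...) {
  cat(sprintf(
    "<trace_spectrum> %d samples: dominant mode %.4g Hz, mean %.2f dB, sd %.2f dB\n",
    x$n, x$dominant_mode, x$mean_db, x$sd_db
  ))
  invisible(x)
}

#' Normalised cross-correlation of two traces
#'
#' Mean-removed, unit-scaled cross-correlation over integer sample lags in
#' `[-max_lag, max_lag]`, normalised by `n * sd(a) * sd(b)` so a trace
#' correlated with itself attains exactly 1 at lag 0. Sign convention: a
#' positive lag means the second trace trails (is delayed relative to) the
#' first, so if `b` is `a` delayed by `k` samples the maximum sits at lag
#' `+k`. Ties on the maximum break toward the smallest `|lag|`.
#'
#' @param a,b [voltage_trace()]s of equal length and sampling interval.
#' @param max_lag Maximum lag in samples; default `floor(n / 4)`.
#' @return An object of class `xcorr_result`: a list with a `lags` tibble
#'   (`lag` in samples, `lag_s` in seconds, `coeff`), scalars `max_coeff`
#'   and `argmax_lag`. Supports `tidy()`, `glance()`, `autoplot()`.
#' @export
cross_correlate <- function(a, b, max_lag = NULL) {
  a <- check_trace(a)
  b <- check_trace(b)
  if (nrow(a) != nrow(b)) {
    stop("traces must have equal length", call. = FALSE)
  }
  if (abs(trace_dt(a) - trace_dt(b)) > 1e-9 * trace_dt(a)) {
    stop("traces must share a sampling interval", call. = FALSE)
  }
  x <- a$voltage
  y <- b$voltage
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a trace: correlation undefined", call. = FALSE)
  }
  if (is.null(max_lag)) max_lag <- floor(n / 4)
  max_lag <- min(max_lag, n - 2L)
  xm <- x - mean(x)
  ym <- y - mean(y)
  denom <- n * sqrt(sum(xm^2) / n) * sqrt(sum(ym^2) / n)
  lags <- (-max_lag):max_lag
  coeff <- vapply(lags, function(k) {
    if (k >= 0) {
      sum(xm[1:(n - k)] * ym[(1 + k):n]) / denom
    } else {
      sum(xm[(1 - k):n] * ym[1:(n + k)]) / denom
    }
  }, numeric(1))
  # ties break toward smallest |lag|
  ord <- order(-coeff, abs(lags))
  best <- ord[1]
  dt <- trace_dt(a)
  structure(
    list(
      lags = tibble::tibble(lag = lags, lag_s = lags * dt, coeff = coeff),
      max_coeff = coeff[best],
      argmax_lag = lags[best],
      n = n
    ),
    class = "xcorr_result"
  )
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf(
    "<xcorr_result> max coefficient %.4f at lag %d samples (n = %d)\n",
    x$max_coeff, x$argmax_lag, x$n
  ))
  invisible(x)
}

#' Two-channel principal component decomposition
#'
#' Eigen-decomposes the 2 x 2 covariance (or correlation, with
#' `standardize = TRUE`) of the paired input/output samples, reporting the
#' variance fractions explained by each component and the projected scores.
#' Collinear pairs give fractions (1, 0); an exactly degenerate covariance
#' (either channel constant) is reported as fractions (1, 0) with a
#' `degenerate` flag rather than an error.
#'
#' @param a,b [voltage_trace()]s of equal length.
#' @param standardize Use the correlation rather than covariance matrix.
#' @return An object of class `trace_pca`: list with `var_fraction`
#'   (length 2, descending, sums to 1), `scores` tibble (`PC1`, `PC2`),
#'   `rotation`, flags `standardize` and `degenerate`. Supports `tidy()`,
#'   `glance()`, `autoplot()`.
#' @export
pca_input_output <- function(a, b, standardize = FALSE) {
  a <- check_trace(a)
  b <- check_trace(b)
  if (nrow(a) != nrow(b)) {
    stop("traces must have equal length", call. = FALSE)
  }
  m <- cbind(input = a$voltage, output = b$voltage)
  sds <- apply(m, 2, stats::sd)
  degenerate <- any(sds == 0)
  if (degenerate && standardize) {
    warning("constant channel: falling back to covariance PCA")
    standardize <- FALSE
  }
  if (all(sds == 0)) {
    return(structure(
      list(
        var_fraction = c(PC1 = 1, PC2 = 0),
        scores = tibble::tibble(PC1 = rep(0, nrow(m)), PC2 = rep(0, nrow(m))),
        rotation = diag(2),
        standardize = standardize,
        degenerate = TRUE,
        n = nrow(m)
      ),
      class = "trace_pca"
    ))
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = standardize)
  vars <- fit$sdev^2
  structure(
    list(
      var_fraction = stats::setNames(vars / sum(vars), c("PC1", "PC2")),
      scores = tibble::as_tibble(fit$x),
      rotation = fit$rotation,
      standardize = standardize,
      degenerate = degenerate,
      n = nrow(m)
    ),
    class = "trace_pca"
  )
}

#' @export
print.trace_pca <- function(x, ...) {
  cat(sprintf(
    "<trace_pca> PC1 %.2f%%, PC2 %.2f%% (%s, n = %d)%s\n",
    100 * x$var_fraction[1], 100 * x$var_fraction[2],
    if (x$standardize) "correlation" else "covariance", x$n,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Savitzky-Golay smoothing of a trace
#'
#' Least-squares local-polynomial (FIR) smoothing. By construction the
#' filter reproduces any polynomial input of degree at most `order`
#' exactly; the defaults (order 2, frame 15) are the settings used to
#' condition traces before Lyapunov analysis.
#'
#' @param trace A [voltage_trace()].
#' @param order Polynomial order (default 2).
#' @param frame Odd window length greater than `order` (default 15).
#' @return A smoothed [voltage_trace()] of equal length.
#' @export
smooth_savgol <- function(trace, order = 2, frame = 15) {
  trace <- check_trace(trace)
  if (frame %% 2 != 1 || frame <= order) {
    stop("`frame` must be odd and greater than `order`", call. = FALSE)
  }
  v <- signal::sgolayfilt(trace$voltage, p = order, n = frame)
  new_voltage_trace(trace$time, v,
    dt = trace_dt(trace),
    label = paste0(trace_label(trace), " -> savgol")
  )
}

#' Largest Lyapunov exponent of a scalar voltage series
#'
#' Estimates the rate of exponential divergence of nearby trajectories from
#' a single voltage series, following the nearest-neighbour tracking idea
#' of Wolf's algorithm. After optional Savitzky-Golay pre-smoothing, each
#' point is paired with its nearest neighbour in voltage subject to two
#' guards: the pair must be separated along the series by at least
#' `step_offset` samples (a Theiler-style window excluding temporally
#' correlated neighbours, 50 by default) and by at least `min_separation`
#' volts (a noise floor, 0.001 V by default). The exponent is the mean
#' one-step log divergence over qualifying pairs,
#' \deqn{\lambda = \langle \ln \frac{|d'| + \epsilon}{|d| + \epsilon}
#'   \rangle,}
#' where \eqn{d} is the pair separation, \eqn{d'} the separation one sample
#' later, and \eqn{\epsilon} a small regulariser guarding the logarithm.
#' Positive values indicate divergence (chaos); negative values indicate
#' convergence of trajectories.
#'
#' `pairing = "offset"` selects an alternative literal pairing in which
#' every pair is taken at the fixed temporal offset `step_offset`. For
#' widely separated, effectively independent pairs this log-ratio averages
#' to zero by stationarity, so the nearest-neighbour rule is the reference
#' interpretation.
#'
#' @param trace A [voltage_trace()] longer than `step_offset + 2`.
#' @param min_separation Minimum pair separation in volts (noise floor).
#' @param step_offset Minimum separation along the series, in samples.
#' @param epsilon Logarithm regulariser (default 1e-5).
#' @param smooth Apply Savitzky-Golay pre-smoothing (default TRUE).
#' @param smooth_order,smooth_frame Savitzky-Golay settings (2, 15).
#' @param pairing `"nearest"` (reference) or `"offset"` (literal fixed
#'   offset).
#' @return An object of class `lyapunov_estimate`: list with
#'   `lambda_per_step` (1/sample), `n_pairs`, and the configuration.
#'   Supports `tidy()` and `glance()`.
#' @examples
#' tr <- generate_logistic(mu = 4, x0 = 0.2, n_iter = 2000)
#' lyapunov_wolf(tr, smooth = FALSE)$lambda_per_step # close to log(2)
#' @export
lyapunov_wolf <- function(trace, min_separation = 0.001, step_offset = 50,
                          epsilon = 1e-5, smooth = TRUE, smooth_order = 2,
                          smooth_frame = 15,
                          pairing = c("nearest", "offset")) {
  trace <- check_trace(trace)
  pairing <- match.arg(pairing)
  if (min_separation <= 0) {
    stop("`min_separation` must be positive", call. = FALSE)
  }
  if (step_offset < 1) stop("`step_offset` must be >= 1", call. = FALSE)
  if (nrow(trace) <= step_offset + 2) {
    stop("trace too short for the requested `step_offset`", call. = FALSE)
  }
  v <- trace$voltage
  if (smooth) {
    v <- signal::sgolayfilt(v, p = smooth_order, n = smooth_frame)
  }
  logs <- if (pairing == "nearest") {
    lyap_pairs_nearest(v, step_offset, min_separation, epsilon)
  } else {
    lyap_pairs_offset(v, step_offset, min_separation, epsilon)
  }
  if (length(logs) == 0) {
    stop(
      "no qualifying pairs: no separations of at least ", min_separation,
      " V at offsets of at least ", step_offset,
      " samples (is the trace constant?)",
      call. = FALSE
    )
  }
  structure(
    list(
      lambda_per_step = mean(logs),
      n_pairs = length(logs),
      config = list(
        min_separation = min_separation, step_offset = step_offset,
        epsilon = epsilon, smooth = smooth, smooth_order = smooth_order,
        smooth_frame = smooth_frame, pairing = pairing
      )
    ),
    class = "lyapunov_estimate"
  )
}

# nearest-in-value neighbour with temporal exclusion, via a sorted walk
lyap_pairs_nearest <- function(v, step_offset, min_sep, eps) {
  n <- length(v)
  idx <- seq_len(n - 1L)
  ord <- order(v[idx])
  sv <- v[idx][ord]
  si <- idx[ord]
  m <- length(ord)
  logs <- numeric(m)
  cnt <- 0L
  for (k in seq_len(m)) {
    i <- si[k]
    bestd <- Inf
    bestj <- NA_integer_
    for (dir in c(-1L, 1L)) {
      p <- k + dir
      while (p >= 1L && p <= m) {
        d <- abs(sv[p] - sv[k])
        if (d >= bestd) break
        j <- si[p]
        if (abs(i - j) >= step_offset && d >= min_sep) {
          bestd <- d
          bestj <- j
          break
        }
        p <- p + dir
      }
    }
    if (!is.na(bestj)) {
      dn <- abs(v[i + 1L] - v[bestj + 1L])
      cnt <- cnt + 1L
      logs[cnt] <- log((dn + eps) / (bestd + eps))
    }
  }
  logs[seq_len(cnt)]
}

lyap_pairs_offset <- function(v, step_offset, min_sep, eps) {
  n <- length(v)
  i <- seq_len(n - step_offset - 1L)
  d <- abs(v[i] - v[i + step_offset])
  dn <- abs(v[i + 1L] - v[i + step_offset + 1L])
  q <- d >= min_sep
  log((dn[q] + eps) / (d[q] + eps))
}

#' @export
print.lyapunov_estimate <- function(x, ...) {
  cat(sprintf(
    "<lyapunov_estimate> lambda = %.6g per step over %d pairs (%s pairing)\n",
    x$lambda_per_step, x$n_pairs, x$config$pairing
  ))
  invisible(x)
}
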