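test_that("peaks per second counts clean cycles exactly", {
  expect_equal(peaks_per_second(sine_trace(freq = 3, duration = 10)), 3.0,
    tolerance = 0.01
  )
  ramp <- voltage_trace(seq(0, 1, 0.01), seq(0, 1, 0.01))
  expect_equal(peaks_per_second(ramp), 0)
  expect_equal(peaks_per_second(constant_trace()), 0)
})

test_that("peak rate is robust to small additive noise on a square wave", {
  set.seed(11)
  # record padded past the last high plateau so all 20 peaks are interior
  t <- seq(0, 10.12, by = 0.001)
  sq <- sign(sin(2 * pi * 2 * t + pi))
  sq[sq == 0] <- -1
  tr <- voltage_trace(t, sq + rnorm(length(t), 0, 0.01))
  expect_equal(peaks_per_second(tr), 2.0, tolerance = 0.05)
})

test_that("trace statistics match the table conventions", {
  s <- trace_stats(constant_trace(0.3))
  expect_equal(s$mean, 0.3)
  expect_equal(s$median, 0.3)
  expect_equal(s$max, 0.3)
  expect_equal(s$min, 0.3)
  expect_equal(s$sd, 0)
  expect_equal(s$dominant_freq, 0)
})

test_that("summaries are translation invariant and affine equivariant", {
  tr <- generate_logistic(n_iter = 800, seed = 3)
  s0 <- trace_stats(tr)
  shifted <- voltage_trace(tr$time + 5, tr$voltage)
  expect_equal(trace_stats(shifted)[, -7], s0[, -7])
  aff <- voltage_trace(tr$time, -2 * tr$voltage + 1)
  sa <- trace_stats(aff)
  expect_equal(sa$mean, -2 * s0$mean + 1)
  expect_equal(sa$median, -2 * s0$median + 1)
  expect_equal(sa$sd, 2 * s0$sd)
  expect_equal(sa$max, -2 * s0$min + 1)
  expect_equal(sa$min, -2 * s0$max + 1)
})

test_that("spectrum finds the dominant mode including DC", {
  dc <- constant_trace(1, n = 256)
  expect_equal(trace_spectrum(dc)$dominant_mode, 0)

  sp <- trace_spectrum(sine_trace(freq = 5, duration = 10, dt = 0.001))
  expect_equal(sp$dominant_mode, 5, tolerance = 0.1)
  bins <- sp$bins
  at5 <- bins$power_db[which.min(abs(bins$freq - 5))]
  others <- bins$power_db[abs(bins$freq - 5) > 0.5]
  expect_gt(at5 - max(others), 20)
})

test_that("spectrum floors log-zero bins at the configured level", {
  sp <- trace_spectrum(constant_trace(0, n = 128), floor_db = -200)
  expect_true(all(sp$bins$power_db >= -200))
  expect_true(all(is.finite(sp$bins$power_db)))
})

test_that("self cross-correlation is exactly 1 at lag 0", {
  tr <- generate_logistic(n_iter = 500, seed = 2)
  xc <- cross_correlate(tr, tr, max_lag = 50)
  expect_equal(xc$max_coeff, 1.0, tolerance = 1e-12)
  expect_identical(xc$argmax_lag, 0L)
})

test_that("a planted delay is recovered at the positive lag", {
  set.seed(4)
  n <- 2000
  base <- as.numeric(stats::filter(rnorm(n + 7), rep(1 / 5, 5), sides = 1))
  base[is.na(base)] <- 0
  k <- 7L
  a <- voltage_trace((1:n) / 100, base[(k + 1):(n + k)])
  b <- voltage_trace((1:n) / 100, base[1:n]) # b trails a by k samples
  xc <- cross_correlate(a, b, max_lag = 30)
  expect_identical(xc$argmax_lag, k)
  expect_gt(xc$max_coeff, 0.9)
})

test_that("cross-correlation rejects degenerate input", {
  expect_error(
    cross_correlate(constant_trace(), constant_trace()),
    "zero variance"
  )
  a <- sine_trace(duration = 1)
  b <- sine_trace(duration = 2)
  expect_error(cross_correlate(a, b), "equal length")
})

test_that("PCA fractions behave at the collinear and isotropic limits", {
  tr <- generate_logistic(n_iter = 1000, seed = 6)
  p <- pca_input_output(tr, tr)
  expect_equal(as.numeric(p$var_fraction), c(1, 0), tolerance = 1e-12)

  set.seed(8)
  n <- 10000
  a <- voltage_trace((1:n) / 100, rnorm(n))
  b <- voltage_trace((1:n) / 100, rnorm(n))
  iso <- pca_input_output(a, b, standardize = TRUE)
  expect_lt(max(abs(as.numeric(iso$var_fraction) - 0.5)), 0.02)

  anti <- voltage_trace(tr$time, -tr$voltage + rnorm(1000, 0, 1e-3))
  expect_gt(pca_input_output(tr, anti)$var_fraction[[1]], 0.99)
})

test_that("PCA fractions sum to one and are order invariant", {
  a <- generate_logistic(n_iter = 500, seed = 10)
  b <- apply_surrogate(a, surrogate_params(gain = 0.1, noise_sd = 0.01, seed = 1))
  p1 <- pca_input_output(a, b)
  p2 <- pca_input_output(b, a)
  expect_equal(sum(p1$var_fraction), 1, tolerance = 1e-9)
  expect_equal(p1$var_fraction, p2$var_fraction, tolerance = 1e-12)
})

test_that("degenerate covariance yields fractions {1, 0} with a record", {
  a <- generate_logistic(n_iter = 100, seed = 1)
  b <- constant_trace(0.1, n = 100)
  p <- pca_input_output(a, b)
  expect_equal(as.numeric(p$var_fraction), c(1, 0), tolerance = 1e-12)
  expect_true(p$degenerate)
})

test_that("savgol reproduces polynomials and reduces noise variance", {
  t <- seq(0, 1, length.out = 201)
  quad <- voltage_trace(t, 2 + 3 * t - 5 * t^2)
  sm <- smooth_savgol(quad, order = 2, frame = 15)
  interior <- 8:194
  expect_equal(sm$voltage[interior], quad$voltage[interior], tolerance = 1e-10)

  nz <- noise_trace(n = 2000, seed = 3)
  expect_lt(sd(smooth_savgol(nz)$voltage), sd(nz$voltage))
  expect_error(smooth_savgol(nz, order = 2, frame = 14), "odd")
})

test_that("savgol impulse response equals the normal-equations kernel", {
  # central row of A (A'A)^-1 A' for order 2, frame 15
  m <- 7
  a_mat <- outer(-m:m, 0:2, "^")
  kern <- (a_mat %*% solve(t(a_mat) %*% a_mat) %*% t(a_mat))[m + 1, ]
  n <- 41
  imp <- voltage_trace(seq_len(n) / 100, as.numeric(seq_len(n) == 21))
  sm <- smooth_savgol(imp, order = 2, frame = 15)
  expect_equal(sm$voltage[(21 - m):(21 + m)], rev(kern), tolerance = 1e-10)
})
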