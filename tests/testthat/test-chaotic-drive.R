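# frozen 10-step hand iteration of x_{n+1} = 4 x_n (1 - x_n) from x0 = 0.2
logistic_mu4_x02 <- c(
  0.2, 0.64, 0.9216, 0.28901376, 0.82193922612265,
  0.585420538734196, 0.970813326249439, 0.113339247303757,
  0.401973849297501, 0.961563495113803
)

test_that("logistic iterates match the hand-iterated recurrence", {
  tr <- generate_logistic(mu = 4, x0 = 0.2, n_iter = 10, v_lo = 0, v_hi = 1)
  expect_equal(tr$voltage, logistic_mu4_x02, tolerance = 1e-12)
})

test_that("logistic fixed point x0 = 1 - 1/mu gives a constant trace", {
  # the fixed point is unstable (|f'| = mu - 2 = 1.8), so floating-point
  # rounding drifts off it geometrically; constancy holds over a short run
  tr <- generate_logistic(mu = 3.8, x0 = 1 - 1 / 3.8, n_iter = 20)
  expect_lt(diff(range(tr$voltage)), 1e-9)
})

test_that("logistic iterates stay in [0, 1] for mu <= 4 and seeded x0", {
  for (seed in 1:5) {
    tr <- generate_logistic(
      mu = 4, n_iter = 10000, v_lo = 0, v_hi = 1, seed = seed
    )
    expect_true(all(tr$voltage >= 0 & tr$voltage <= 1))
  }
})

test_that("logistic domain errors are raised", {
  expect_error(generate_logistic(mu = 4.2), "diverges")
  expect_error(generate_logistic(x0 = 1.5), "\\(0, 1\\)")
  expect_error(generate_logistic(x0 = 0), "\\(0, 1\\)")
})

test_that("baker orbit matches the hand-iterated standard map", {
  # alpha = 0.5 from (0.3, 0.4): x follows the period-3 doubling cycle
  tr_x <- generate_baker(
    alpha = 0.5, x0 = 0.3, y0 = 0.4, n_iter = 10, v_lo = 0, v_hi = 1
  )
  expect_equal(
    tr_x$voltage,
    c(0.3, 0.6, 0.2, 0.4, 0.8, 0.6, 0.2, 0.4, 0.8, 0.6),
    tolerance = 1e-12
  )
  tr_y <- generate_baker(
    alpha = 0.5, x0 = 0.3, y0 = 0.4, n_iter = 10, v_lo = 0, v_hi = 1,
    component = "y"
  )
  expect_equal(
    tr_y$voltage,
    c(0.4, 0.2, 0.6, 0.3, 0.15, 0.575, 0.7875, 0.39375, 0.196875, 0.5984375),
    tolerance = 1e-12
  )
})

test_that("baker origin is a fixed point and output respects the range", {
  tr <- generate_baker(x0 = 0, y0 = 0, n_iter = 50, v_lo = -0.5, v_hi = 0.5)
  expect_true(all(tr$voltage == -0.5))
  tr2 <- generate_baker(
    alpha = 0.3, x0 = 0.77, y0 = 0.13, n_iter = 5000, v_lo = -2, v_hi = 1
  )
  expect_true(all(tr2$voltage >= -2 & tr2$voltage <= 1))
  expect_error(generate_baker(x0 = 1.2), "unit square")
})

test_that("lorenz defaults give a bounded 10,001-sample chaotic trace", {
  tr <- generate_lorenz()
  expect_equal(nrow(tr), 10001)
  expect_true(max(abs(tr$voltage)) < 25) # attractor confinement
  expect_gt(diff(range(tr$voltage)), 10)
})

test_that("lorenz with sigma = 0 freezes the x component", {
  tr <- generate_lorenz(
    sigma = 0, y0 = c(2, 2, 0), duration = 5, scale = 3
  )
  expect_equal(unique(tr$voltage), 6)
})

test_that("rossler all-zero start with b = 0 stays at the origin", {
  tr <- generate_rossler(b = 0, y0 = c(0, 0, 0), duration = 5)
  expect_true(all(tr$voltage == 0))
})

test_that("rossler defaults oscillate with positive peak-to-peak range", {
  tr <- generate_rossler(duration = 50)
  expect_gt(diff(range(tr$voltage)), 5)
  expect_gt(peaks_per_second(tr), 0)
})

test_that("coarse RK4 trajectories track an independent fine oracle", {
  # oracle: adaptive lsoda at tight tolerance, first 10 s
  oracle <- function(deriv, y0, parms) {
    deSolve::ode(y0, seq(0, 10, 0.01), deriv, parms,
      method = "lsoda", rtol = 1e-10, atol = 1e-10
    )
  }
  lorenz_d <- function(t, s, p) {
    list(c(
      p$sigma * (s[2] - s[1]), s[1] * (p$rho - s[3]) - s[2],
      s[1] * s[2] - p$beta * s[3]
    ))
  }
  ref <- oracle(lorenz_d, c(0, 1, 1.05), list(sigma = 10, rho = 28, beta = 8 / 3))
  got <- generate_lorenz(duration = 10)
  expect_lt(max(abs(got$voltage - ref[, 2])), 1e-2)

  rossler_d <- function(t, s, p) {
    list(c(-s[2] - s[3], s[1] + p$a * s[2], p$b + s[3] * (s[1] - p$c)))
  }
  ref <- oracle(rossler_d, c(1, 1, 1), list(a = 0.2, b = 0.2, c = 5.7))
  got <- generate_rossler(duration = 10)
  expect_lt(max(abs(got$voltage - ref[, 2])), 1e-2)
})

test_that("RK4 reproduces the exponential decay closed form", {
  out <- protact:::integrate_rk4(
    function(t, s, p) list(-s), 1, dt = 0.01, duration = 5, parms = NULL
  )
  expect_equal(out[, 2], exp(-out[, 1]), tolerance = 1e-8)
})

test_that("fhn drive selects quiescence at c = 1 and spiking at c = 2", {
  quiet <- generate_fhn(c = 1, duration = 300)
  spiking <- generate_fhn(c = 2, duration = 300)
  expect_lt(tail_p2p(quiet), 0.01)
  expect_gt(tail_p2p(spiking), 0.5)
})

test_that("fhn limit-cycle period is step-size robust to 1%", {
  period <- function(dt) {
    tr <- generate_fhn(c = 2, duration = 600, dt = dt)
    v <- tr$voltage[seq.int(floor(nrow(tr) / 2), nrow(tr))]
    pk <- which(diff(sign(diff(v))) < 0) + 1
    pk <- pk[v[pk] > mean(v)]
    mean(diff(pk)) * dt
  }
  p_coarse <- period(0.01)
  p_fine <- period(0.001)
  expect_lt(abs(p_coarse - p_fine) / p_fine, 0.01)
})

test_that("fhn returns both state variables when asked", {
  both <- generate_fhn(c = 2, duration = 20, component = "both")
  expect_named(both, c("time", "v", "w"))
  w <- generate_fhn(c = 2, duration = 20, component = "w")
  expect_equal(w$voltage, both$w)
})

test_that("pulse trains are reproducible and encode bits as levels", {
  a <- generate_pulse_train(n_bits = 10, seed = 42)
  b <- generate_pulse_train(n_bits = 10, seed = 42)
  expect_identical(a$trace$voltage, b$trace$voltage)
  expect_identical(a$bits$bit, b$bits$bit)

  ones <- generate_pulse_train(bits = rep(1, 5))
  expect_true(all(ones$trace$voltage == 0.5))

  enc <- generate_pulse_train(
    bits = c(1, 0, 1), bit_dt = 0.1, pulse_width = 0.1
  )
  expect_equal(enc$trace$voltage, c(0.5, -0.5, 0.5))
  expect_error(
    generate_pulse_train(bit_dt = 0.01, pulse_width = 0.001),
    "at least"
  )
})

test_that("generators are pure functions of their parameters", {
  expect_identical(
    generate_logistic(n_iter = 100, seed = 3)$voltage,
    generate_logistic(n_iter = 100, seed = 3)$voltage
  )
  expect_identical(
    generate_lorenz(duration = 2)$voltage,
    generate_lorenz(duration = 2)$voltage
  )
})
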