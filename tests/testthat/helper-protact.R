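# fixture builders shared across the suite

sine_trace <- function(freq = 5, duration = 10, dt = 0.001, amplitude = 1,
                       phase = 0) {
  t <- seq(0, duration, by = dt)
  voltage_trace(t, amplitude * sin(2 * pi * freq * t + phase), label = "sine")
}

constant_trace <- function(value = 0.3, n = 100, dt = 0.01) {
  voltage_trace((seq_len(n) - 1) * dt, rep(value, n), label = "constant")
}

# seeded white-noise trace
noise_trace <- function(n = 1000, sd = 1, dt = 0.01, seed = 1) {
  set.seed(seed)
  voltage_trace((seq_len(n) - 1) * dt, rnorm(n, 0, sd), label = "noise")
}

# seeded random bit stream
random_bits <- function(n, seed) {
  set.seed(seed)
  bit_stream(as.integer(runif(n) >= 0.5), dt = 1)
}

# late-time peak-to-peak amplitude (last `frac` of the trace)
tail_p2p <- function(trace, frac = 0.2) {
  v <- trace$voltage
  tail_v <- v[seq.int(floor(length(v) * (1 - frac)) + 1, length(v))]
  diff(range(tail_v))
}
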