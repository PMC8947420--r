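# shared fixtures, built in code

tone <- function(freq_hz, fs, duration_s, amplitude = 1, phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  uniform_signal(amplitude * sin(2 * pi * freq_hz * t + phase), dt = 1 / fs)
}

# independent scripted Tiecks recursion (kept deliberately separate from the
# package internals; written directly from the two-state difference equations)
oracle_tiecks <- function(dP, dt, T, D, K) {
  x1 <- 0; x2 <- 0
  v <- numeric(length(dP))
  for (i in seq_along(dP)) {
    x2n <- x2 + (x1 - 2 * D * x2) * dt / T
    x1 <- x1 + (dP[i] - x2) * dt / T
    x2 <- x2n
    v[i] <- 1 + dP[i] - K * x2
  }
  v
}

quiet_spec <- function(...) synthetic_cohort_spec(...)
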