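# Shared fixtures: the default broadcast and its receiver reference are
# computed once per test run; echoes are synthesized by a deliberately
# plain insertion loop kept independent of the package's synthesizer.

bn_chirp <- chirp_params()
bn_broadcast <- generate_broadcast(bn_chirp)
bn_ref <- broadcast_reference(bn_broadcast)

# Sum of delayed, scaled broadcast copies plus optional white noise.
make_glint_echo <- function(delays, amps = 1, snr_db = Inf, pad = 2.5e-3) {
  fs <- bn_broadcast$sample_rate
  b <- bn_broadcast$samples
  amps <- rep_len(amps, length(delays))
  n <- ceiling((max(delays) + pad) * fs) + length(b) + 1
  x <- numeric(n)
  for (j in seq_along(delays)) {
    d <- delays[j] * fs
    k <- floor(d); f <- d - k
    i <- seq_along(b)
    x[i + k] <- x[i + k] + amps[j] * (1 - f) * b
    x[i + k + 1] <- x[i + k + 1] + amps[j] * f * b
  }
  if (is.finite(snr_db)) x <- x + stats::rnorm(n, 0, max(amps) * 10^(-snr_db / 20))
  waveform(x, fs)
}

# Analytic two-glint interference minima on a band: |1 + exp(-2i*pi*f*dt)|
# vanishes at f = (k + 1/2) / dt.
analytic_null_freqs <- function(dt, f_lo = 20e3, f_hi = 100e3) {
  k <- 0:ceiling(f_hi * dt)
  f <- (k + 0.5) / dt
  f[f >= f_lo & f <= f_hi]
}

# End-on two-way glint delay of a scene target, seconds.
scene_spacing_s <- function(scene, id) {
  tg <- Find(function(t) t$id == id, scene$targets)
  2 * tg$glint_spacing / scene$sound_speed
}
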