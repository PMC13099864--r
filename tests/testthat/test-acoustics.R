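test_that("broadcast sweeps linearly from 100 down to 20 kHz", {
  b <- bn_broadcast
  fs <- b$sample_rate
  # instantaneous frequency from zero-crossing intervals near each end
  zc <- function(x) which(x[-length(x)] < 0 & x[-1] >= 0)
  inst_freq <- function(win) {
    z <- zc(b$samples[win])
    (length(z) - 1) / (diff(range(z)) / fs)
  }
  # sweep rate is 40 kHz/ms, so a 0.2 ms window averages 4 kHz inside the end
  n <- length(b$samples)
  f0 <- inst_freq(1:200)                # first 0.2 ms: mean ~ 96 kHz
  f1 <- inst_freq((n - 200):n)          # last 0.2 ms: mean ~ 24 kHz
  expect_equal(f0, 96e3, tolerance = 0.03)
  expect_equal(f1, 24e3, tolerance = 0.05)
  expect_error(chirp_params(f_start = 5e4, f_end = 5e4), "f_start > f_end")
  expect_error(chirp_params(sample_rate = 3e5), "sample_rate")
})

test_that("spectrogram ridge of the broadcast follows the analytic sweep law", {
  env <- bn_ref$env
  pk <- batnav:::channel_ridge(env)
  cf <- env$center_freqs
  t_analytic <- (cf - bn_chirp$f_start) /
    ((bn_chirp$f_end - bn_chirp$f_start) / bn_chirp$duration)
  mid <- cf >= 30e3 & cf <= 90e3        # away from the taper ends
  expect_lt(max(abs(pk$time[mid] - t_analytic[mid])), 50e-6)
  # peak times decrease monotonically with frequency for a downward sweep
  expect_true(all(diff(pk$time[mid]) < 0))
})

test_that("two-way delay scales as 2/c per metre of range", {
  expect_equal(round(range_to_delay(1, 344) * 1e3, 1), 5.8)
  expect_equal(range_to_delay(0), 0)
  expect_equal(range_to_delay(1.5, 340), 2 * 1.5 / 340)
  expect_error(range_to_delay(-1), "non-negative")
})

test_that("binaural synthesis produces geometric delays, ITD and glint spacing", {
  sc <- build_scene(list(list(position = c(0, 1.5), spacing_s = 100e-6)))
  es <- synthesize_binaural_echoes(sc, sc$bat_init, bn_broadcast,
                                   snr_db = Inf)
  # dead ahead: both ears hear the first glint simultaneously
  expect_lt(abs(es$truth$delay_left - es$truth$delay_right), 1e-6)
  # the near glint of an observer-facing target sits half a spacing closer
  expect_equal(es$truth$delay_left, 2 * (1.5 - 0.017 / 2) / 340,
               tolerance = 1e-4)
  # per-ear glint separation is the end-on 100 us
  expect_equal(es$truth$glint_dt, 100e-6, tolerance = 1e-2)
  # matched filter on the raw waveform finds the first glint
  expect_equal(matched_filter_delay(es$left, bn_broadcast),
               es$truth$delay_left, tolerance = 1e-3)

  # 30 deg off the beam: interaural delay difference ~ a sin(theta) / c
  sc30 <- build_scene(list(list(position = 2 * c(sin(pi / 6), cos(pi / 6)),
                                spacing_s = 100e-6)))
  es30 <- synthesize_binaural_echoes(sc30, sc30$bat_init, bn_broadcast,
                                     snr_db = Inf)
  itd <- es30$truth$delay_left - es30$truth$delay_right
  expect_equal(itd, 0.014 * sin(pi / 6) / 340, tolerance = 2e-3)
  # odd symmetry: mirror target gives the negated difference
  scm <- build_scene(list(list(position = 2 * c(-sin(pi / 6), cos(pi / 6)),
                               spacing_s = 100e-6)))
  esm <- synthesize_binaural_echoes(scm, scm$bat_init, bn_broadcast,
                                    snr_db = Inf)
  expect_equal(esm$truth$delay_left - esm$truth$delay_right, -itd,
               tolerance = 1e-9)
})

test_that("echoes superpose: a two-target mixture is the sum of the singles", {
  specs <- list(list(position = c(-0.5, 1.2), spacing_s = 100e-6),
                list(position = c(0.8, 2.1), spacing_s = 300e-6))
  sc <- build_scene(specs)
  both <- synthesize_binaural_echoes(sc, sc$bat_init, bn_broadcast,
                                     snr_db = Inf, pad_s = 1e-3)
  one <- synthesize_binaural_echoes(sc, sc$bat_init, bn_broadcast,
                                    snr_db = Inf, include = 1, pad_s = 1e-3)
  two <- synthesize_binaural_echoes(sc, sc$bat_init, bn_broadcast,
                                    snr_db = Inf, include = 2, pad_s = 1e-3)
  n <- length(both$left$samples)
  pad <- function(x) c(x, numeric(n - length(x)))
  expect_equal(both$left$samples,
               pad(one$left$samples) + pad(two$left$samples))
  expect_equal(both$right$samples,
               pad(one$right$samples) + pad(two$right$samples))
})

test_that("waveforms round-trip through WAV files", {
  sc <- build_scene(list(list(position = c(0.3, 1.0), spacing_s = 100e-6)))
  es <- synthesize_binaural_echoes(sc, sc$bat_init, bn_broadcast,
                                   snr_db = Inf)
  path <- tempfile(fileext = ".wav")
  write_wav(es, path)
  rt <- read_wav(path)
  expect_equal(rt$left$sample_rate, es$left$sample_rate)
  expect_equal(rt$left$samples, es$left$samples, tolerance = 1e-6)
  expect_equal(rt$right$samples, es$right$samples, tolerance = 1e-6)
  unlink(path)
})
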