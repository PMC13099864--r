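test_that("threshold events: silence yields an all-absent matrix", {
  env <- filterbank_spectrogram(waveform(numeric(5000), 1e6))
  ev <- detect_events(env, reference = 1)
  expect_true(all(is.na(ev$first)))
  expect_equal(nrow(ev$crossings), 0)
})

test_that("raw crossings of higher thresholds occur later within a channel", {
  e <- make_glint_echo(4e-3)
  env <- filterbank_spectrogram(e)
  ev <- detect_events(env)
  raw <- sweep(ev$first, 1, ifelse(is.finite(ev$latency), ev$latency, 0))
  for (ci in seq(5, 75, by = 10)) {
    r <- raw[ci, ]
    r <- r[!is.na(r)]
    if (length(r) > 1) expect_true(all(diff(r) >= 0))
  }
})

test_that("scaling the envelope advances crossings and trades 6 dB of latency", {
  e <- make_glint_echo(4e-3, amps = 0.3)
  env <- filterbank_spectrogram(e)
  env2 <- env
  env2$env <- env$env * 2
  ref <- max(env$env) * 4          # fixed external reference for both
  ev1 <- detect_events(env, reference = ref)
  ev2 <- detect_events(env2, reference = ref)
  both <- !is.na(ev1$first) & !is.na(ev2$first)
  expect_gt(sum(both), 100)
  expect_true(all(ev2$first[both] <= ev1$first[both] + 1e-12))
  lat_drop <- ev1$latency - ev2$latency
  fin <- is.finite(lat_drop) & ev1$latency > 0 & ev2$latency > 0
  expect_equal(unname(lat_drop[fin]),
               rep(15e-6 * 20 * log10(2), sum(fin)), tolerance = 1e-6)
})

test_that("a two-glint echo retards events at the null channels (scalloping)", {
  e <- make_glint_echo(c(6e-3, 6.1e-3))
  env <- filterbank_spectrogram(e)
  ev <- detect_events(env)
  d <- dechirp(ev, bn_ref$events)
  raw <- d$residual_raw
  null_ch <- vapply(analytic_null_freqs(100e-6), function(f)
    which.min(abs(env$center_freqs - f)), integer(1))
  anti_ch <- vapply(analytic_null_freqs(100e-6) + 5e3, function(f)
    which.min(abs(env$center_freqs - f)), integer(1))
  med_null <- stats::median(raw[null_ch, ], na.rm = TRUE)
  med_anti <- stats::median(raw[anti_ch, ], na.rm = TRUE)
  expect_gt(med_null - med_anti, 50e-6)
})

test_that("dechirping collapses the sweep and is translation-equivariant", {
  # broadcast against itself: every defined cell is ~0
  d0 <- dechirp(bn_ref$events, bn_ref$events)
  expect_lt(max(abs(d0$residual), na.rm = TRUE), 1e-12)

  e <- make_glint_echo(6e-3)
  ev <- detect_events(filterbank_spectrogram(e))
  d <- dechirp(ev, bn_ref$events)
  expect_equal(stats::median(d$residual, na.rm = TRUE), 6e-3,
               tolerance = 1e-3)
  # shifting all echo events by 1 ms shifts every residual by exactly 1 ms
  ev_shift <- ev
  ev_shift$first <- ev$first + 1e-3
  ev_shift$crossings$time <- ev$crossings$time + 1e-3
  d_shift <- dechirp(ev_shift, bn_ref$events)
  expect_equal(d_shift$residual, d$residual + 1e-3)

  bad <- bn_ref$events
  bad$first <- bad$first[1:10, , drop = FALSE]
  expect_error(dechirp(ev, bad), "grid")
})

test_that("pooled delay estimation is a trimmed mean with a confidence score", {
  v <- 4.2e-3
  d <- structure(list(residual = matrix(v, 40, 10)),
                 class = "dechirped_events")
  est <- estimate_overall_delay(d)
  expect_equal(est$delay, v)
  expect_equal(est$confidence, 1)

  few <- structure(list(residual = matrix(c(v, rep(NA, 79)), 8, 10)),
                   class = "dechirped_events")
  est2 <- estimate_overall_delay(few)
  expect_true(is.na(est2$delay))
})
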