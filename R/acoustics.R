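# Acoustics: FM broadcast synthesis and binaural echo mixtures.

#' FM chirp parameters
#'
#' The model broadcast is a linear FM sweep running downward from `f_start`
#' to `f_end` (defaults 100 kHz to 20 kHz), tapered at both ends with a
#' raised-cosine ramp.  Pulse duration is not a published constant; 2 ms is
#' typical of the short FM pulses of the modelled species and keeps the
#' broadcast shorter than typical echo delays.  The 1 MHz sample rate gives
#' 1 us resolution, ten times the top frequency.
#'
#' @param f_start start (high) frequency, Hz.
#' @param f_end end (low) frequency, Hz.
#' @param duration pulse duration, seconds.
#' @param sample_rate samples per second; must be at least `4 * f_start`.
#' @param taper fraction of the duration tapered with a raised cosine at
#'   each end.
#' @return an object of class `chirp_params`.
#' @export
chirp_params <- function(f_start = 100e3, f_end = 20e3, duration = 2e-3,
                         sample_rate = 1e6, taper = 0.05) {
  if (!(f_start > f_end && f_end > 0))
    stop("need f_start > f_end > 0 for a downward FM sweep")
  if (sample_rate < 4 * f_start)
    stop("sample_rate must be at least 4 * f_start")
  stopifnot(duration > 0, taper >= 0, taper < 0.5)
  structure(list(f_start = f_start, f_end = f_end, duration = duration,
                 sample_rate = sample_rate, taper = taper),
            class = "chirp_params")
}

#' Sampled waveform
#'
#' @param samples numeric vector.
#' @param sample_rate Hz.
#' @param t0 time of the first sample relative to pulse emission, seconds.
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate, t0 = 0) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 t0 = t0), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g kHz, t0 = %.3f ms, %.2f ms long\n",
              length(x$samples), x$sample_rate / 1e3, x$t0 * 1e3,
              length(x$samples) / x$sample_rate * 1e3))
  invisible(x)
}

#' Generate the FM broadcast
#'
#' Linear FM chirp whose instantaneous frequency runs from `f_start` at
#' t = 0 to `f_end` at t = duration, amplitude-tapered at both ends.
#'
#' @param params a [chirp_params()].
#' @return a [waveform()] with `t0 = 0`.
#' @export
generate_broadcast <- function(params = chirp_params()) {
  stopifnot(inherits(params, "chirp_params"))
  n <- round(params$duration * params$sample_rate)
  t <- (seq_len(n) - 1) / params$sample_rate
  k <- (params$f_end - params$f_start) / params$duration  # sweep rate, Hz/s
  phase <- 2 * pi * (params$f_start * t + 0.5 * k * t^2)
  x <- sin(phase)
  nt <- max(1, round(params$taper * n))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nt) - 0.5) / nt))
  x[seq_len(nt)] <- x[seq_len(nt)] * ramp
  x[n + 1 - seq_len(nt)] <- x[n + 1 - seq_len(nt)] * ramp
  waveform(x, params$sample_rate, t0 = 0)
}

#' Two-way delay for a target range
#'
#' @param range_m target range in metres (>= 0).
#' @param sound_speed m/s.
#' @return the two-way travel time `2 * range_m / sound_speed` in seconds.
#' @export
range_to_delay <- function(range_m, sound_speed = 340) {
  if (any(range_m < 0)) stop("range must be non-negative")
  2 * range_m / sound_speed
}

# Add a delayed, scaled copy of `pulse` into `buf` (two-tap linear
# interpolation carries sub-sample delay).
add_delayed <- function(buf, pulse, delay_s, fs, amp) {
  d <- delay_s * fs
  k <- floor(d)
  f <- d - k
  i <- seq_along(pulse)
  buf[i + k] <- buf[i + k] + amp * (1 - f) * pulse
  buf[i + k + 1] <- buf[i + k + 1] + amp * f * pulse
  buf
}

#' Synthesize binaural echoes for one epoch
#'
#' Every target in the front hemisphere of the beam contributes one delayed,
#' scaled copy of the broadcast per glint and per ear.  Ears sit at
#' `position +/- (ear_separation / 2)` along the perpendicular to the beam
#' heading; per-ear delays are exact two-point path lengths
#' (mouth -> glint -> ear), so interaural differences and aspect-projected
#' glint spacings both emerge from the geometry.  Propagation losses are
#' deliberately not modelled; optional white Gaussian noise is set by an SNR
#' relative to a single glint reflection of reflectivity 1.
#'
#' @param scene a `scat_scene`.
#' @param bat a [bat_state()].
#' @param broadcast the emitted [waveform()].
#' @param snr_db signal-to-noise ratio in dB re a unit glint reflection;
#'   `Inf` (noise off) for exact tests.
#' @param include optional integer indices of targets to synthesize
#'   (default: all in the front hemisphere of the beam).
#' @param pad_s extra quiet time appended after the last echo, seconds.
#' @return an object of class `ear_signals`: list with `left` and `right`
#'   [waveform()]s and `truth`, a data frame with one row per contributing
#'   target: first-glint delays per ear, projected glint delay, bearing.
#' @export
synthesize_binaural_echoes <- function(scene, bat, broadcast, snr_db = 40,
                                       include = NULL, pad_s = 0.5e-3) {
  stopifnot(inherits(scene, "scat_scene"), inherits(bat, "bat_state"),
            inherits(broadcast, "waveform"))
  fs <- broadcast$sample_rate
  mouth <- bat$position
  left_perp <- rotate_ccw(bat$beam_heading, 90)
  ear_l <- mouth + (scene$ear_separation / 2) * left_perp
  ear_r <- mouth - (scene$ear_separation / 2) * left_perp

  if (is.null(include)) {
    # rear-hemisphere targets (relative to the beam) do not echo back
    include <- which(vapply(scene$targets, function(t)
      sum((t$position - mouth) * bat$beam_heading) > 0, logical(1)))
  }
  truth <- data.frame(id = character(0), delay_left = numeric(0),
                      delay_right = numeric(0), glint_dt = numeric(0),
                      bearing_deg = numeric(0), range_m = numeric(0))
  delays <- list()
  for (i in include) {
    tg <- scene$targets[[i]]
    g <- glint_points(tg, mouth)
    dl <- dr <- numeric(2)
    for (j in 1:2) {
      out <- vec_norm(g[j, ] - mouth)
      dl[j] <- (out + vec_norm(ear_l - g[j, ])) / scene$sound_speed
      dr[j] <- (out + vec_norm(ear_r - g[j, ])) / scene$sound_speed
    }
    delays[[length(delays) + 1]] <-
      list(l = dl, r = dr, amp = tg$reflectivity)
    # positive bearing = target right of the beam (clockwise)
    bearing <- -signed_angle(bat$beam_heading, tg$position - mouth)
    truth[nrow(truth) + 1, ] <-
      list(tg$id, min(dl), min(dr),
           (abs(diff(dl)) + abs(diff(dr))) / 2,
           bearing, vec_norm(tg$position - mouth))
  }
  max_delay <- if (length(delays))
    max(vapply(delays, function(d) max(d$l, d$r), numeric(1))) else 0
  n <- ceiling((max_delay + pad_s) * fs) + length(broadcast$samples) + 2
  left <- right <- numeric(n)
  for (d in delays) {
    for (j in 1:2) {
      left <- add_delayed(left, broadcast$samples, d$l[j], fs, d$amp)
      right <- add_delayed(right, broadcast$samples, d$r[j], fs, d$amp)
    }
  }
  if (is.finite(snr_db)) {
    sd_n <- 10^(-snr_db / 20)  # re unit glint reflection amplitude
    left <- left + stats::rnorm(n, 0, sd_n)
    right <- right + stats::rnorm(n, 0, sd_n)
  }
  structure(list(left = waveform(left, fs, 0),
                 right = waveform(right, fs, 0),
                 truth = truth),
            class = "ear_signals")
}

#' Matched-filter delay oracle
#'
#' Cross-correlates an ear signal with the broadcast and returns the delay
#' of the earliest correlation peak within `top_db` of the global maximum
#' (so a two-glint echo of equal reflectivities reports its first glint).
#' This is the conventional-receiver reference against which the
#' spectrogram-based delay estimate is checked; it is not used inside the
#' receiver.
#'
#' @param echo,broadcast [waveform()]s at the same sample rate.
#' @param top_db peaks within this many dB of the maximum count as
#'   candidates.
#' @return delay in seconds.
#' @export
matched_filter_delay <- function(echo, broadcast, top_db = 1) {
  stopifnot(echo$sample_rate == broadcast$sample_rate)
  fs <- echo$sample_rate
  n <- length(echo$samples) + length(broadcast$samples)
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(echo$samples, numeric(nfft - length(echo$samples))))
  H <- stats::fft(c(broadcast$samples,
                    numeric(nfft - length(broadcast$samples))))
  cc <- Re(stats::fft(X * Conj(H), inverse = TRUE)) / nfft
  cc <- cc[seq_len(length(echo$samples))]  # non-negative lags only
  env <- abs(cc)
  thr <- max(env) * 10^(-top_db / 20)
  # earliest local maximum above threshold
  cand <- which(env >= thr)
  loc <- cand[cand > 1 & cand < length(env)]
  loc <- loc[env[loc] >= env[loc - 1] & env[loc] >= env[loc + 1]]
  k <- if (length(loc)) min(loc) else which.max(env)
  # parabolic refinement on the correlation envelope
  if (k > 1 && k < length(env)) {
    y1 <- env[k - 1]; y2 <- env[k]; y3 <- env[k + 1]
    denom <- (y1 - 2 * y2 + y3)
    off <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  } else off <- 0
  (k - 1 + off) / fs + echo$t0 - broadcast$t0
}

#' Write a waveform (or stereo pair) as a WAV file
#'
#' Minimal 32-bit IEEE float PCM writer/reader for inspection of model
#' signals in external audio tools; kept deliberately simple (no compressed
#' or integer formats).
#'
#' @param x a [waveform()] or an `ear_signals` object (written as 2-channel).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  if (inherits(x, "ear_signals")) {
    ch <- rbind(x$left$samples, x$right$samples)
    fs <- x$left$sample_rate
  } else if (inherits(x, "waveform")) {
    ch <- matrix(x$samples, nrow = 1)
    fs <- x$sample_rate
  } else stop("x must be a waveform or ear_signals")
  n_ch <- nrow(ch)
  data <- as.numeric(ch)  # interleaved by column
  con <- file(path, "wb")
  on.exit(close(con))
  bytes <- length(data) * 4
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(3), con, size = 2, endian = "little")  # IEEE float
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4 * n_ch), con, size = 4, endian = "little")
  writeBin(as.integer(4 * n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(32), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(bytes), con, size = 4, endian = "little")
  writeBin(data, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF/WAV file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 8) != "WAVEfmt ") stop("unsupported WAV layout")
  fmt_len <- readBin(con, "integer", 1, 4, endian = "little")
  fmt <- readBin(con, "integer", 1, 2, endian = "little")
  if (fmt != 3) stop("only 32-bit float WAV supported")
  n_ch <- readBin(con, "integer", 1, 2, endian = "little")
  fs <- readBin(con, "integer", 1, 4, endian = "little")
  invisible(readBin(con, "raw", fmt_len - 8))
  if (readChar(con, 4) != "data") stop("unsupported WAV layout")
  bytes <- readBin(con, "integer", 1, 4, endian = "little")
  data <- readBin(con, "numeric", bytes / 4, size = 4, endian = "little")
  if (n_ch == 1) return(waveform(data, fs))
  m <- matrix(data, nrow = n_ch)
  structure(list(left = waveform(m[1, ], fs), right = waveform(m[2, ], fs),
                 truth = NULL), class = "ear_signals")
}
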