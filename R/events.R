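# Threshold detection events, dechirping, and pooled delay estimation.

#' Default detection threshold levels
#'
#' Ten levels logarithmically spaced from 30 dB to 3 dB below the reference
#' peak, expressed as amplitude fractions.  The level count is fixed by the
#' model; the values are configuration.
#'
#' @param n number of levels.
#' @param db_floor,db_ceiling range below the reference peak, dB.
#' @return numeric vector of amplitude fractions, strictly increasing.
#' @export
default_threshold_levels <- function(n = 10, db_floor = 30, db_ceiling = 3) {
  10^(-seq(db_floor, db_ceiling, length.out = n) / 20)
}

#' Detect threshold-crossing events
#'
#' For every channel and threshold level, records the times at which the
#' channel envelope crosses the level upward (linearly interpolated between
#' envelope samples).  Levels are fractions of a reference amplitude
#' (default: the envelope peak of this segment).  Amplitude-latency trading
#' is emulated by retarding every event of a channel by
#' `latency_coeff * (dB of the channel peak below the reference)`: weaker
#' channels register later, which is what carves the scalloped pattern
#' around spectral nulls.
#'
#' @param env a `channel_envelopes` object.
#' @param levels strictly increasing amplitude fractions (default
#'   [default_threshold_levels()]).
#' @param latency_coeff amplitude-latency trading slope, seconds per dB
#'   (default 15 us/dB, within the physiological range).
#' @param reference reference amplitude; default `max(env$env)`.
#' @param max_crossings cap on recorded upward crossings per channel/level.
#' @return an object of class `event_matrix`: `first` is a
#'   `channels x levels` matrix of first-crossing times (seconds, `NA` where
#'   the envelope never reaches the level), `crossings` a data frame of all
#'   recorded events (`channel`, `level`, `time`), plus the channel ridge
#'   times/amplitudes and bookkeeping fields.
#' @export
detect_events <- function(env, levels = default_threshold_levels(),
                          latency_coeff = 15e-6, reference = NULL,
                          max_crossings = 12) {
  stopifnot(inherits(env, "channel_envelopes"))
  if (any(diff(levels) <= 0)) stop("threshold levels must be strictly increasing")
  e <- env$env
  n_ch <- nrow(e)
  n_lev <- length(levels)
  reference <- reference %||% max(e)
  if (reference <= 0) reference <- 1
  thr <- reference * levels
  # detection sits above the noise floor: the echo ridge is sparse in the
  # analysis window, so the median envelope estimates the noise level, and
  # thresholds below ~5x it would fire on noise alone and flood the event
  # matrix with spurious registrations
  noise_floor <- 5 * stats::median(e)
  thr <- pmax(thr, noise_floor)
  dt <- 1 / env$env_rate
  tt0 <- env$t0
  ridge <- channel_ridge(env)
  # latency penalty per channel from its peak amplitude
  db_below <- ifelse(ridge$amp > 0,
                     pmax(0, 20 * log10(reference / pmax(ridge$amp, 1e-300))),
                     Inf)
  lat <- latency_coeff * db_below

  lat_fin <- ifelse(is.finite(lat), lat, 0)
  nT <- ncol(e)
  first <- matrix(NA_real_, n_ch, n_lev)
  ch_l <- lev_l <- tim_l <- vector("list", n_lev)
  for (li in seq_len(n_lev)) {
    th <- thr[li]
    cmp <- e >= th
    # genuine upward crossings only; a segment already above threshold at
    # its first sample is a cropped echo and carries no usable onset
    w <- which(!cmp[, -nT, drop = FALSE] & cmp[, -1, drop = FALSE],
               arr.ind = TRUE)
    if (!nrow(w)) next
    ch <- w[, 1]
    idx <- w[, 2]
    e0 <- e[cbind(ch, idx)]
    tm <- tt0 + (idx - 1 + (th - e0) / (e[cbind(ch, idx + 1)] - e0)) * dt +
      lat_fin[ch]
    o <- order(ch, tm)
    ch <- ch[o]; tm <- tm[o]
    k <- sequence(rle(ch)$lengths)  # per-channel crossing index
    keep <- k <= max_crossings
    ch <- ch[keep]; tm <- tm[keep]; k <- k[keep]
    first[cbind(ch[k == 1L], li)] <- tm[k == 1L]
    ch_l[[li]] <- ch
    lev_l[[li]] <- rep.int(li, length(ch))
    tim_l[[li]] <- tm
  }
  crossings <- data.frame(channel = unlist(ch_l) %||% integer(0),
                          level = unlist(lev_l) %||% integer(0),
                          time = unlist(tim_l) %||% numeric(0))
  structure(list(first = first, crossings = crossings, levels = levels,
                 reference = reference, latency_coeff = latency_coeff,
                 latency = lat, center_freqs = env$center_freqs,
                 ridge_time = ridge$time, ridge_amp = ridge$amp,
                 smoothing_time = env$params$smoothing_time),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %d channels x %d levels, %d defined cells, %d crossings\n",
              nrow(x$first), ncol(x$first), sum(!is.na(x$first)),
              nrow(x$crossings)))
  invisible(x)
}

#' Dechirp echo events against the broadcast
#'
#' Subtracts the broadcast's per-channel/per-level first-crossing times from
#' the echo's event times, collapsing the FM sweep so that a delayed copy of
#' the broadcast lands on a single residual delay in every cell.
#'
#' @param events echo [detect_events()] output.
#' @param broadcast_events broadcast [detect_events()] output on the same
#'   channel/level grid.
#' @return an object of class `dechirped_events` with two
#'   `channels x levels` residual matrices (`NA` where either input is
#'   absent): `residual_raw` keeps the amplitude-latency retardation (the
#'   scalloped pattern used to localise nulls), while `residual` removes the
#'   known per-channel latency terms of both segments so that a delayed copy
#'   of the broadcast collapses to its true delay (the latency-corrected
#'   registration used for delay pooling).  `crossings` carries every echo
#'   crossing with its corrected residual.
#' @export
dechirp <- function(events, broadcast_events) {
  stopifnot(inherits(events, "event_matrix"),
            inherits(broadcast_events, "event_matrix"))
  if (!identical(dim(events$first), dim(broadcast_events$first)) ||
      !isTRUE(all.equal(events$center_freqs, broadcast_events$center_freqs)))
    stop("event matrices are on different channel/level grids")
  b <- broadcast_events$first
  # per-channel latency-trading terms of each segment
  lat_e <- ifelse(is.finite(events$latency), events$latency, 0)
  lat_b <- ifelse(is.finite(broadcast_events$latency),
                  broadcast_events$latency, 0)
  lat_diff <- lat_e - lat_b
  residual_raw <- events$first - b
  residual <- residual_raw - lat_diff
  cr <- events$crossings
  if (nrow(cr)) {
    bref <- b[cbind(cr$channel, cr$level)]
    cr$residual <- cr$time - bref - lat_diff[cr$channel]
    cr <- cr[!is.na(cr$residual), , drop = FALSE]
  } else cr$residual <- numeric(0)
  structure(list(residual = residual, residual_raw = residual_raw,
                 crossings = cr,
                 center_freqs = events$center_freqs,
                 broadcast_ridge = broadcast_events$ridge_time,
                 smoothing_time = events$smoothing_time),
            class = "dechirped_events")
}

#' Pooled overall-delay estimate (spectrogram correlation)
#'
#' Robust location estimate of the dechirped first-crossing residuals over
#' all defined channel/level cells; the frequency-by-frequency delay
#' registrations are pooled into a single echo delay.
#'
#' @param d a [dechirp()] result.
#' @param min_cells minimum number of defined cells required (default 10);
#'   fewer means "no echo detected" and an `NA` estimate.
#' @param trim trim fraction for the trimmed mean.
#' @param conf_window half-width (seconds) of the agreement window used for
#'   the confidence score.
#' @return list with `delay` (seconds or `NA`), `confidence` (fraction of
#'   defined cells within `conf_window` of the estimate) and `n_cells`.
#' @export
estimate_overall_delay <- function(d, min_cells = 10, trim = 0.25,
                                   conf_window = 50e-6) {
  stopifnot(inherits(d, "dechirped_events"))
  r <- d$residual[!is.na(d$residual)]
  if (length(r) < min_cells)
    return(list(delay = NA_real_, confidence = 0, n_cells = length(r)))
  delay <- mean(r, trim = trim)
  list(delay = delay,
       confidence = mean(abs(r - delay) <= conf_window),
       n_cells = length(r))
}
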