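# Spectral interference nulls and their inversion to glint delay
# (the "transformation" half of the receiver).

#' Extract spectral interference nulls
#'
#' Two glint reflections closer together than the integration time merge
#' into one echo whose spectrum carries interference nulls spaced 1/dt in
#' frequency.  The nulls are located as local minima of the per-channel echo
#' amplitude profile (the envelope peak of each channel inside the echo's
#' ridge window), with sub-channel refinement by parabolic interpolation.
#' Channels around a null are also maximally retarded by amplitude-latency
#' trading; that event-timing pattern is used as a cross-check: a candidate
#' minimum is kept only if the dechirped event residuals of its channel are
#' retarded relative to the across-channel median (or yielded no events at
#' all).
#'
#' @param d a [dechirp()] result for the echo.
#' @param env the echo `channel_envelopes`.
#' @param delay overall echo delay (seconds); default
#'   [estimate_overall_delay()] on `d`.
#' @param min_prominence minimum prominence of a null as a fraction of the
#'   profile maximum.
#' @param min_spacing minimum spacing between nulls, Hz.
#' @param edge_guard band margin, Hz: candidate nulls closer than this to
#'   the band edges are discarded, because the broadcast's amplitude taper
#'   shades those channels and biases minima there.
#' @param retard_check logical; apply the event-retardation cross-check.
#' @return an object of class `null_pattern`: `null_freqs` (Hz, sorted),
#'   `profile` (per-channel amplitudes), `band`.
#' @export
extract_nulls <- function(d, env, delay = NULL, min_prominence = 0.05,
                          min_spacing = 2e3, edge_guard = 4.4e3,
                          retard_check = TRUE) {
  stopifnot(inherits(d, "dechirped_events"), inherits(env, "channel_envelopes"))
  if (is.null(delay)) delay <- estimate_overall_delay(d)$delay
  cf <- env$center_freqs
  empty <- structure(list(null_freqs = numeric(0),
                          profile = rep(NA_real_, length(cf)),
                          center_freqs = cf, band = range(cf)),
                     class = "null_pattern")
  if (is.na(delay)) return(empty)
  # spectral profile: channel peak amplitude inside the echo ridge window
  w <- 1.5 * env$params$smoothing_time
  centre <- d$broadcast_ridge + delay
  nt <- ncol(env$env)
  i_lo <- pmax(1, floor((centre - w - env$t0) * env$env_rate) + 1)
  i_hi <- pmin(nt, ceiling((centre + w - env$t0) * env$env_rate) + 1)
  prof <- vapply(seq_along(cf), function(ci) {
    if (is.na(centre[ci]) || i_hi[ci] < i_lo[ci]) return(NA_real_)
    max(env$env[ci, i_lo[ci]:i_hi[ci]])
  }, numeric(1))
  ok <- is.finite(prof)
  if (sum(ok) < 5) return(empty)
  pmax_ <- max(prof[ok])
  if (pmax_ <= 0) return(empty)
  # local minima of the profile = peaks of the inverted profile
  inv <- pmax_ - ifelse(ok, prof, pmax_)
  pk <- pracma::findpeaks(inv, minpeakheight = 0,
                          minpeakdistance = max(1, round(min_spacing /
                                                         env$params$spacing)),
                          zero = "-")
  if (is.null(pk)) return(empty)
  # prominence relative to the higher neighbouring shoulder of the profile
  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    k <- pk[i, 2]
    lo <- pk[i, 3]; hi <- pk[i, 4]
    shoulder <- min(max(prof[lo:k], na.rm = TRUE),
                    max(prof[k:hi], na.rm = TRUE))
    keep[i] <- (shoulder - prof[k]) >= min_prominence * pmax_
  }
  pk <- pk[keep, , drop = FALSE]
  if (!nrow(pk)) return(empty)
  idx <- sort(pk[, 2])
  idx <- idx[cf[idx] >= min(cf) + edge_guard & cf[idx] <= max(cf) - edge_guard]
  if (!length(idx)) return(empty)
  if (retard_check && nrow(d$crossings) > 0) {
    # events at a null channel lag those of its shoulder channels
    # (amplitude-latency trading); compare within this echo's own cluster
    # of raw residuals so other echoes in the window cannot skew the test
    n_ch <- length(cf)
    local_res <- function(ci) {
      r <- d$residual_raw[ci, ]
      r[!is.na(r) & r - delay > -4e-4 & r - delay < 9e-4]
    }
    retarded <- vapply(idx, function(k) {
      rk <- local_res(k)
      if (!length(rk)) return(TRUE)  # fully suppressed: consistent with a null
      sh <- c(unlist(lapply(max(1, k - 4):max(1, k - 2), local_res)),
              unlist(lapply(min(n_ch, k + 2):min(n_ch, k + 4), local_res)))
      if (!length(sh)) return(TRUE)
      stats::median(rk) >= stats::median(sh) - 5e-6
    }, logical(1))
    idx <- idx[retarded]
  }
  if (!length(idx)) return(empty)
  # parabolic sub-channel refinement on the profile minimum
  freqs <- vapply(idx, function(k) {
    if (k <= 1 || k >= length(prof) || !ok[k - 1] || !ok[k + 1])
      return(cf[k])
    y1 <- prof[k - 1]; y2 <- prof[k]; y3 <- prof[k + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (den != 0) 0.5 * (y1 - y3) / den else 0
    cf[k] + max(-0.5, min(0.5, off)) * env$params$spacing
  }, numeric(1))
  structure(list(null_freqs = sort(freqs), profile = prof,
                 center_freqs = cf, band = range(cf)),
            class = "null_pattern")
}

#' @export
print.null_pattern <- function(x, ...) {
  if (!length(x$null_freqs)) cat("<null_pattern> no nulls\n")
  else cat("<null_pattern>", length(x$null_freqs), "nulls at",
           paste(signif(x$null_freqs / 1e3, 4), collapse = ", "), "kHz\n")
  invisible(x)
}

#' Invert null spacings to a glint delay
#'
#' The frequency spacing of adjacent interference nulls is the reciprocal of
#' the glint-reflection time separation (`df = 1/dt`); the estimate is
#' `1 / mean(adjacent null spacing)`.  When a weak null goes undetected the
#' gap across it doubles; gaps larger than 1.6 times the smallest gap are
#' therefore excluded from the mean (a no-op when all nulls are present).
#'
#' A single gap (two nulls) carries no evidence that the pattern is
#' periodic, so at least three nulls are required; the smallest glint delay
#' in play (30 us) still leaves three nulls inside the 20-100 kHz band.
#'
#' @param nulls a [extract_nulls()] result, or a numeric vector of null
#'   frequencies in Hz.
#' @return estimated glint delay in seconds, or `NA` when fewer than three
#'   nulls are available.
#' @export
transform_nulls_to_glint <- function(nulls) {
  f <- if (inherits(nulls, "null_pattern")) nulls$null_freqs else nulls
  if (length(f) < 3) return(NA_real_)
  gaps <- diff(sort(f))
  keep <- gaps <= 1.6 * min(gaps)
  1 / mean(gaps[keep])
}
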