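# Binaural localisation and the pursuit controller.

#' Navigation / control parameters
#'
#' Defaults give single-target runs the characteristic curved approach:
#' the sonar beam can swing 60 deg per epoch and fixates within an epoch or
#' two, while the flight heading is limited to 15 deg per epoch and lags
#' behind the beam.  None of these constants are published values; all are
#' exposed here.
#'
#' @param ear_separation metres (default 14 mm).
#' @param max_flight_turn flight-heading turn limit, deg/epoch.
#' @param max_beam_turn beam-aim turn limit, deg/epoch (must exceed
#'   `max_flight_turn`).
#' @param speed forward speed, m/epoch (0.1 m/epoch is about 1 m/s at a
#'   10 Hz pulse rate, which reproduces the characteristic ~20-epoch
#'   single-target approach from 1.5 m).
#' @param classify_azimuth_gate classify only when the target sits within
#'   this many degrees of the beam axis, so the glint spacing is measured
#'   with minimal aspect distortion; 8 deg leaves room for the one-epoch
#'   parallax between aiming and moving while costing under 1% in aspect
#'   projection.
#' @param accept_tolerance accept a target whose glint delay is within this
#'   many seconds of the desired spacing (default 20 us).
#' @param capture_radius metres; the accepted target is "captured" when the
#'   bat passes within this distance.
#' @param min_confidence minimum delay-estimate confidence for a
#'   classification decision.
#' @param classify_confirm number of consecutive epochs that must agree
#'   before an accept/reject verdict commits; 2 makes the decision robust to
#'   a single distorted look.
#' @param lost_retries re-emissions tolerated before a candidate that stops
#'   producing usable estimates is dropped.
#' @return an object of class `nav_params`.
#' @export
nav_params <- function(ear_separation = 0.014, max_flight_turn = 15,
                       max_beam_turn = 60, speed = 0.1,
                       classify_azimuth_gate = 8, accept_tolerance = 20e-6,
                       capture_radius = 0.1, min_confidence = 0.25,
                       classify_confirm = 2, lost_retries = 3) {
  stopifnot(max_beam_turn > max_flight_turn, max_flight_turn > 0,
            accept_tolerance > 0, speed > 0, capture_radius > 0)
  structure(list(ear_separation = ear_separation,
                 max_flight_turn = max_flight_turn,
                 max_beam_turn = max_beam_turn, speed = speed,
                 classify_azimuth_gate = classify_azimuth_gate,
                 accept_tolerance = accept_tolerance,
                 capture_radius = capture_radius,
                 min_confidence = min_confidence,
                 classify_confirm = classify_confirm,
                 lost_retries = lost_retries),
            class = "nav_params")
}

#' Azimuth from the binaural delay difference
#'
#' `azimuth = arcsin(c * (left_delay - right_delay) / ear_separation)`,
#' positive when the target lies to the right of the beam axis (the right
#' ear hears it first).  Differences exceeding the physical maximum
#' `ear_separation / c` are clamped to +/-90 deg and flagged.
#'
#' @param left_delay,right_delay echo delays at the two ears, seconds.
#' @param p a [nav_params()].
#' @param sound_speed m/s.
#' @return azimuth in degrees with attribute `clamped` (logical).
#' @export
binaural_azimuth <- function(left_delay, right_delay, p = nav_params(),
                             sound_speed = 340) {
  s <- sound_speed * (left_delay - right_delay) / p$ear_separation
  clamped <- abs(s) > 1
  s <- pmax(-1, pmin(1, s))
  structure(rad2deg(asin(s)), clamped = clamped)
}

#' Binaural delay disparity of one reflection
#'
#' The interaural delay difference is measured cell by cell: every
#' channel/threshold cell whose dechirped residual falls within `window` of
#' the reflection's delay in both ears contributes its left-minus-right
#' residual difference, and the median is taken.  Pairing the same cells
#' across ears cancels the interference and threshold distortions common to
#' both, which single-ear pooled delays do not.
#'
#' @param estL,estR [analyze_echo()] estimates for the left and right ear.
#' @param delay the reflection delay to pair on, seconds.
#' @param window pairing half-window, seconds (default the integration
#'   time).
#' @param min_cells minimum number of paired cells.
#' @return left-minus-right delay difference in seconds, or `NA`.
#' @export
binaural_delay_difference <- function(estL, estR, delay, window = 350e-6,
                                      min_cells = 5) {
  cell_res <- function(est) {
    cr <- est$crossings
    if (is.null(cr) || nrow(cr) == 0) return(NULL)
    cr <- cr[abs(cr$residual - delay) < window, , drop = FALSE]
    if (nrow(cr) == 0) return(NULL)
    cr <- cr[order(abs(cr$residual - delay)), , drop = FALSE]
    cr <- cr[!duplicated(cr[, c("channel", "level")]), , drop = FALSE]
    stats::setNames(cr$residual, paste(cr$channel, cr$level))
  }
  rL <- cell_res(estL)
  rR <- cell_res(estR)
  if (is.null(rL) || is.null(rR)) return(NA_real_)
  common <- intersect(names(rL), names(rR))
  if (length(common) < min_cells) return(NA_real_)
  stats::median(rL[common] - rR[common])
}

#' Select the nearest candidate target
#'
#' The search always engages the target with the shortest echo delay among
#' candidates not yet rejected this scene; ties break toward the lower id.
#'
#' @param candidates data frame with columns `id` and `delay` (seconds).
#' @param rejected character vector of ids already rejected.
#' @return the selected row of `candidates`, or `NULL` when the scene is
#'   exhausted (no unrejected candidate remains).
#' @export
select_nearest <- function(candidates, rejected = character(0)) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  cand <- candidates[!(candidates$id %in% rejected), , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(cand$delay, cand$id), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Steer the beam aim toward an estimated azimuth
#'
#' Rotates the beam heading toward the target bearing (current beam axis
#' offset by `azimuth_est`) by at most `max_beam_turn` degrees.
#'
#' @param state a [bat_state()].
#' @param azimuth_est degrees, positive = right of the beam.
#' @param p a [nav_params()].
#' @return the updated `bat_state`.
#' @export
update_beam_aim <- function(state, azimuth_est, p = nav_params()) {
  turn <- sign(azimuth_est) * min(abs(azimuth_est), p$max_beam_turn)
  state$beam_heading <- rotate_ccw(state$beam_heading, -turn)  # +az = clockwise
  state
}

#' Advance the flight one epoch
#'
#' The flight heading turns toward the beam heading by at most
#' `max_flight_turn` degrees (the rate-of-turn limit that keeps flight paths
#' smooth and lagging behind the beam), then the bat advances by `speed`
#' along the new heading and the epoch counter increments.
#'
#' @param state a [bat_state()].
#' @param p a [nav_params()].
#' @return the updated `bat_state`.
#' @export
update_flight <- function(state, p = nav_params()) {
  state$flight_heading <- turn_toward(state$flight_heading,
                                      state$beam_heading, p$max_flight_turn)
  state$position <- state$position + p$speed * state$flight_heading
  state$epoch_index <- state$epoch_index + 1L
  state
}

#' Classify the tracked target
#'
#' Classification happens only once the beam is aligned (azimuth inside the
#' gate), so the glint spacing is observed with minimal distortion: accept
#' when the merged-spectrum glint delay lies within `accept_tolerance` of
#' the desired spacing and the echo did not resolve into separate
#' reflections; reject otherwise.  An unusable estimate (no echo, or no
#' delay) yields `"lost"` so the caller can re-emit and eventually drop the
#' candidate.
#'
#' @param est a [analyze_echo()] `glint_estimate` (or `NULL`).
#' @param azimuth_est degrees.
#' @param p a [nav_params()].
#' @param desired desired glint delay, seconds.
#' @return one of `"approach"`, `"accept"`, `"reject"`, `"lost"`.
#' @export
classify_target <- function(est, azimuth_est, p = nav_params(),
                            desired = 100e-6) {
  if (is.null(est) || is.na(est$overall_delay)) return("lost")
  if (is.na(azimuth_est) || abs(azimuth_est) > p$classify_azimuth_gate)
    return("approach")
  if (length(est$secondary_delays) > 1) return("reject")
  if (is.na(est$glint_dt)) return("lost")
  if (abs(est$glint_dt - desired) <= p$accept_tolerance) "accept" else "reject"
}
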