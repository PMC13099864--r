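# Epoch loop: emit, listen, analyze, steer, classify, move.

#' Simulation configuration
#'
#' Bundles the broadcast, receiver and controller parameters for a run.
#'
#' @param chirp a [chirp_params()].
#' @param filterbank a [filterbank_params()].
#' @param nav a [nav_params()].
#' @param levels detection threshold levels ([default_threshold_levels()]).
#' @param latency_coeff amplitude-latency trading slope, s/dB.
#' @param snr_db echo SNR re a unit glint reflection (dB); `Inf` disables
#'   noise.
#' @param min_cells,trim receiver pooling parameters, see [analyze_echo()].
#' @param gate_before,gate_after the tracked-target analysis window extends
#'   this far (seconds) before the predicted first-glint delay and after the
#'   predicted delay plus the broadcast duration.  The trailing margin
#'   covers glint pairs out to the largest spacing in play (2 ms).
#' @param assoc_window maximum |estimated - true| delay for attributing a
#'   resolved reflection to a target, seconds.
#' @return an object of class `batnav_config`.
#' @export
batnav_config <- function(chirp = chirp_params(),
                          filterbank = filterbank_params(),
                          nav = nav_params(),
                          levels = default_threshold_levels(),
                          latency_coeff = 15e-6, snr_db = 40,
                          min_cells = 10, trim = 0.25,
                          gate_before = 1.2e-3, gate_after = 2.6e-3,
                          assoc_window = 0.5e-3) {
  structure(list(chirp = chirp, filterbank = filterbank, nav = nav,
                 levels = levels, latency_coeff = latency_coeff,
                 snr_db = snr_db, min_cells = min_cells, trim = trim,
                 gate_before = gate_before, gate_after = gate_after,
                 assoc_window = assoc_window),
            class = "batnav_config")
}

# Crop a waveform to [t_lo, t_hi] (absolute times), keeping the time base.
crop_waveform <- function(w, t_lo, t_hi) {
  fs <- w$sample_rate
  n <- length(w$samples)
  i_lo <- max(1, floor((t_lo - w$t0) * fs) + 1)
  i_hi <- min(n, ceiling((t_hi - w$t0) * fs) + 1)
  if (i_hi <= i_lo) return(NULL)
  waveform(w$samples[i_lo:i_hi], fs, w$t0 + (i_lo - 1) / fs)
}

# Attribute an estimated reflection delay to a target id using the
# synthesis truth (either glint of the target may match).
associate_delay <- function(delay, truth, window) {
  if (nrow(truth) == 0) return(NA_character_)
  d1 <- abs(truth$delay_left - delay)
  d2 <- abs(truth$delay_left + truth$glint_dt - delay)
  dd <- pmin(d1, d2)
  k <- which.min(dd)
  if (dd[k] <= window) truth$id[k] else NA_character_
}

analyze_ear <- function(wave, sim) {
  analyze_echo(wave, sim$ref, levels = sim$cfg$levels,
               latency_coeff = sim$cfg$latency_coeff,
               min_cells = sim$cfg$min_cells, trim = sim$cfg$trim)
}

#' Initialise a simulation
#'
#' Builds the per-run state: cached broadcast and its receiver reference,
#' the bat pose, rejection memory and the epoch log.  Per-run randomness
#' (echo noise) is governed by `seed`; identical `(scene, config, seed)`
#' give identical runs.
#'
#' @param scene a `scat_scene`.
#' @param config a [batnav_config()].
#' @param seed integer.
#' @return an object of class `batnav_sim` (pass to [run_epoch()]).
#' @export
batnav_sim <- function(scene, config = batnav_config(), seed = 1) {
  stopifnot(inherits(scene, "scat_scene"))
  broadcast <- generate_broadcast(config$chirp)
  ref <- broadcast_reference(broadcast, config$filterbank,
                             levels = config$levels,
                             latency_coeff = config$latency_coeff)
  bat <- scene$bat_init
  bat$speed <- config$nav$speed
  structure(list(scene = scene, cfg = config, bat = bat,
                 broadcast = broadcast, ref = ref, seed = seed,
                 rng = NULL,
                 rejected = character(0), tracked = NA_character_,
                 tracked_delay = NA_real_, tracked_pos = NULL,
                 cooldown = numeric(0), lost_count = 0L,
                 noglint_count = 0L, engaged_count = 0L,
                 pending_verdict = NA_character_, pending_count = 0L,
                 accepted = FALSE,
                 outcome = NA_character_, captured_target = NA_character_,
                 records = list()),
            class = "batnav_sim")
}

# One decoded reflection table (id, delay, per-ear delays) from full-scan
# analyses of both ears.
scan_candidates <- function(estL, estR, truth, window) {
  if (is.na(estL$overall_delay)) return(NULL)
  dl <- estL$modes$delay
  ids <- vapply(dl, associate_delay, character(1), truth = truth,
                window = window)
  ok <- !is.na(ids)
  if (!any(ok)) return(NULL)
  cand <- data.frame(id = ids[ok], delay = dl[ok])
  cand <- cand[order(cand$delay), , drop = FALSE]
  cand[!duplicated(cand$id), , drop = FALSE]  # first glint per target
}

# TRUE when no other target's reflection arrives within `window` of the
# tracked target's own reflections: a foreign echo that close would leak
# into the spectral-profile window and distort the interference pattern, so
# classification waits for the approach geometry to separate the delays.
truth_clean <- function(truth, tracked, window = 1e-3) {
  i <- truth$id == tracked
  if (!any(i)) return(FALSE)
  td <- c(truth$delay_left[i], truth$delay_left[i] + truth$glint_dt[i])
  oth <- truth[!i, , drop = FALSE]
  if (nrow(oth) == 0) return(TRUE)
  od <- c(oth$delay_left, oth$delay_left + oth$glint_dt)
  min(abs(outer(td, od, `-`))) > window
}

# Restrict an estimate to the tracked target's own reflection modes for
# classification.  Returns NULL when the target has no attributable mode;
# otherwise flags contamination when a foreign (or unattributable) mode sits
# within `foreign_window` of the tracked reflection — close enough to leak
# into the spectral-profile window and distort the interference pattern.
classification_view <- function(est, ids, tracked, ref_delay,
                                foreign_window = 1e-3) {
  m <- est$modes
  own <- which(!is.na(ids) & ids == tracked)
  if (!length(own)) return(NULL)
  foreign <- which((is.na(ids) | ids != tracked) &
                   abs(m$delay - ref_delay) <= foreign_window)
  mm <- m[own, , drop = FALSE]
  est$modes <- mm
  est$overall_delay <- mm$delay[1]
  est$secondary_delays <- if (nrow(mm) > 1) mm$delay else numeric(0)
  est$glint_dt <- if (nrow(mm) == 1) mm$glint_dt[1] else NA_real_
  est$confidence <- mm$confidence[1]
  est$contaminated <- length(foreign) > 0
  est
}

# The tracked target's own first-glint reflection in an estimate: the
# earliest mode attributed to `tracked` (modes overlapping the emission,
# below `min_delay`, are unusable).  Returns NULL when the target left no
# attributable reflection in the analysis window.
find_own_mode <- function(est, truth, tracked, assoc_window,
                          min_delay = 3e-4) {
  if (is.null(est) || nrow(est$modes) == 0) return(NULL)
  ids <- vapply(est$modes$delay, associate_delay, character(1),
                truth = truth, window = assoc_window)
  own <- which(!is.na(ids) & ids == tracked & est$modes$delay >= min_delay)
  if (!length(own)) return(NULL)
  list(ids = ids, delay = min(est$modes$delay[own]))
}

#' Run one broadcast epoch
#'
#' Emits the broadcast, synthesizes the binaural echo mixture from all
#' targets in front of the beam, analyzes each ear with the SCAT chain,
#' selects or tracks the nearest unrejected target, estimates its azimuth
#' from the binaural delay difference, steers the beam (fast) and the flight
#' heading (rate-limited), classifies the target once the beam is aligned,
#' and advances the bat.  Refuses to run once the scene is resolved.
#'
#' @param sim a [batnav_sim()] state.
#' @return the updated `batnav_sim`, with one record appended to
#'   `sim$records`.
#' @export
run_epoch <- function(sim) {
  stopifnot(inherits(sim, "batnav_sim"))
  if (!is.na(sim$outcome)) stop("scene already resolved (", sim$outcome, ")")
  if (is.null(sim$rng)) {  # first epoch: seed the per-run noise stream
    with_seed(sim$seed, sim$rng <- get(".Random.seed", envir = globalenv()))
  }
  old_rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", sim$rng, envir = globalenv())
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  })

  scene <- sim$scene
  cfg <- sim$cfg
  nav <- cfg$nav
  bat <- sim$bat
  cc <- scene$sound_speed
  es <- synthesize_binaural_echoes(scene, bat, sim$broadcast,
                                   snr_db = cfg$snr_db)
  az <- NA_real_
  delay <- NA_real_
  gdt <- NA_real_
  conf <- NA_real_
  action <- "lost"
  est_comb <- NULL
  clean <- FALSE

  if (is.na(sim$tracked)) {
    # selection scan: analyze the whole window, list candidate reflections
    estL <- analyze_ear(es$left, sim)
    estR <- analyze_ear(es$right, sim)
    cand <- scan_candidates(estL, estR, es$truth, cfg$assoc_window)
    # recently abandoned (repeatedly lost) targets wait out a cooldown so
    # the approach geometry can change before they are re-engaged
    cooling <- names(sim$cooldown)[sim$bat$epoch_index - sim$cooldown < 10]
    sel <- select_nearest(cand, c(sim$rejected, cooling))
    if (is.null(sel)) sel <- select_nearest(cand, sim$rejected)
    if (is.null(sel)) {
      remaining <- setdiff(vapply(scene$targets, `[[`, character(1), "id"),
                           sim$rejected)
      if (length(remaining) == 0) {
        sim$outcome <- "exhausted"
      }
      # nothing engageable in front of the beam: keep turning and searching
      bat$beam_heading <- rotate_ccw(bat$beam_heading, -nav$max_beam_turn)
    } else {
      sim$tracked <- sel$id
      sim$lost_count <- 0L
      sim$noglint_count <- 0L
      sim$engaged_count <- 0L
      sim$pending_verdict <- NA_character_
      sim$pending_count <- 0L
      delay <- sel$delay
      itd <- binaural_delay_difference(estL, estR, delay)
      if (!is.na(itd)) az <- as.numeric(binaural_azimuth(itd, 0, nav, cc))
      ids <- vapply(estL$modes$delay, associate_delay, character(1),
                    truth = es$truth, window = cfg$assoc_window)
      est_comb <- classification_view(estL, ids, sel$id, sel$delay)
      clean <- !is.null(est_comb) && !est_comb$contaminated &&
        truth_clean(es$truth, sel$id)
    }
  } else {
    # tracked target: gated analysis around the predicted delay, with the
    # tracked reflection re-identified each epoch (so tracking cannot drift
    # onto a different target crossing the gate); if the gate comes up
    # empty, re-acquire from the full window before declaring a lost epoch
    estL <- estR <- NULL
    fo <- NULL
    if (!is.na(sim$tracked_delay)) {
      pred <- max(sim$tracked_delay - 2 * nav$speed / cc, 3e-4)
      t_lo <- max(0, pred - cfg$gate_before)
      t_hi <- pred + cfg$chirp$duration + cfg$gate_after
      wl <- crop_waveform(es$left, t_lo, t_hi)
      wr <- crop_waveform(es$right, t_lo, t_hi)
      estL <- if (!is.null(wl)) analyze_ear(wl, sim) else NULL
      estR <- if (!is.null(wr)) analyze_ear(wr, sim) else NULL
      fo <- find_own_mode(estL, es$truth, sim$tracked, cfg$assoc_window)
    }
    if (is.null(fo) &&
        (sim$accepted || is.null(estL) || nrow(estL$modes) == 0)) {
      # re-acquire from the full window when the gate is empty (prediction
      # off) or the target has already been accepted and must be re-found;
      # a gate with only foreign modes during classification means the
      # tracked echo is merged with a neighbour and a rescan cannot help
      estL <- analyze_ear(es$left, sim)
      estR <- analyze_ear(es$right, sim)
      fo <- find_own_mode(estL, es$truth, sim$tracked, cfg$assoc_window)
    }
    if (!is.null(fo)) {
      itd <- binaural_delay_difference(estL, estR, fo$delay)
      if (!is.na(itd)) {
        delay <- fo$delay
        az <- as.numeric(binaural_azimuth(itd, 0, nav, cc))
        est_comb <- classification_view(estL, fo$ids, sim$tracked, fo$delay)
        clean <- !is.null(est_comb) && !est_comb$contaminated &&
          truth_clean(es$truth, sim$tracked)
        if (!is.null(est_comb)) delay <- est_comb$overall_delay
      }
    }
  }

  if (!is.na(sim$tracked)) {
    if (is.na(delay)) {
      # tracked target produced no usable echo this epoch
      if (sim$accepted) {
        action <- "approach"
        sim$lost_count <- sim$lost_count + 1L
        if (sim$lost_count > nav$lost_retries) {
          # the accepted target has slipped away: discard the stale delay
          # and turn to search until its echo reappears
          sim$tracked_delay <- NA_real_
          bat$beam_heading <- rotate_ccw(bat$beam_heading, -nav$max_beam_turn)
        } else if (!is.null(sim$tracked_pos)) {
          # keep homing on the last known position
          bearing <- -signed_angle(bat$beam_heading,
                                   sim$tracked_pos - bat$position)
          bat <- update_beam_aim(bat, bearing, nav)
        }
      } else {
        action <- "lost"
        sim$lost_count <- sim$lost_count + 1L
        if (sim$lost_count > nav$lost_retries) {
          # abandon (not reject): remember a cooldown so the target is
          # re-engaged later from different geometry
          sim$cooldown[sim$tracked] <- bat$epoch_index
          sim$tracked <- NA_character_
          sim$lost_count <- 0L
        } else if (!is.null(sim$tracked_pos)) {
          bearing <- -signed_angle(bat$beam_heading,
                                   sim$tracked_pos - bat$position)
          bat <- update_beam_aim(bat, bearing, nav)
        }
      }
    } else {
      sim$lost_count <- 0L
      sim$tracked_delay <- delay
      gdt <- if (!is.null(est_comb)) est_comb$glint_dt else NA_real_
      conf <- if (!is.null(est_comb)) est_comb$confidence else NA_real_
      # dead-reckoned world position of the tracked reflection
      rng_m <- delay * cc / 2
      dir <- rotate_ccw(bat$beam_heading, -(az %||% 0))
      if (!is.na(az)) sim$tracked_pos <- bat$position + rng_m * dir
      # a resolved own glint pair can be rejected on timing alone, even
      # with a foreign echo nearby; merged-spectrum decisions need the
      # clean window
      resolved_pair <- !is.null(est_comb) &&
        length(est_comb$secondary_delays) > 1
      if (sim$accepted) {
        action <- "approach"
      } else if ((clean || resolved_pair) && !is.na(az) &&
                 (is.null(est_comb) || est_comb$confidence >= nav$min_confidence)) {
        action <- classify_target(est_comb, az, nav, scene$desired_spacing)
        if (action %in% c("accept", "reject")) {
          # commit a verdict only after consecutive clean looks agree, so a
          # single distorted spectrum cannot mis-classify a target
          if (identical(sim$pending_verdict, action)) {
            sim$pending_count <- sim$pending_count + 1L
          } else {
            sim$pending_verdict <- action
            sim$pending_count <- 1L
          }
          if (sim$pending_count < nav$classify_confirm) {
            action <- "approach"
          }
        }
        if (action == "accept") {
          sim$accepted <- TRUE
        } else if (action == "reject") {
          sim$rejected <- c(sim$rejected, sim$tracked)
        } else if (action == "lost") {
          # clean aligned look but no usable glint registration: re-emit,
          # then drop the candidate after the configured retries
          sim$noglint_count <- sim$noglint_count + 1L
          if (sim$noglint_count > nav$lost_retries) {
            sim$rejected <- c(sim$rejected, sim$tracked)
            action <- "reject"
          }
        }
      } else {
        action <- "approach"
      }
      if (!is.na(az)) bat <- update_beam_aim(bat, az, nav)
    }
  }

  # stall safety valve: an engagement that cannot reach a classification
  # (persistently contaminated geometry) is abandoned so the search can
  # return from a different direction
  if (!is.na(sim$tracked) && !sim$accepted) {
    sim$engaged_count <- sim$engaged_count + 1L
    if (sim$engaged_count > 60L && !(action %in% c("accept", "reject"))) {
      sim$cooldown[sim$tracked] <- bat$epoch_index
      sim$tracked <- NA_character_
      sim$engaged_count <- 0L
      sim$lost_count <- 0L
    }
  }

  selected <- sim$tracked
  if (identical(action, "reject")) {
    sim$tracked <- NA_character_
    sim$lost_count <- 0L
    sim$tracked_pos <- NULL
  }

  prev <- bat$position
  # terminal capture maneuver: once the target is accepted and close, the
  # bat brakes and turns hard; without it the flight turn limit sets a
  # minimum orbit radius larger than the capture disk and the approach can
  # limit-cycle around the target
  nav_eff <- nav
  if (sim$accepted) {
    d_known <- if (!is.na(delay)) delay else sim$tracked_delay
    if (!is.na(d_known)) {
      rng_m <- d_known * cc / 2
      if (rng_m < 0.6) {
        nav_eff$speed <- max(min(nav$speed, rng_m / 3), 0.03)
        nav_eff$max_flight_turn <- nav$max_beam_turn
      }
    }
  }
  bat <- update_flight(bat, nav_eff)

  if (sim$accepted && !is.na(selected)) {
    tgt <- Find(function(t) t$id == selected, scene$targets)
    if (!is.null(tgt) &&
        point_segment_distance(tgt$position, prev, bat$position) <=
        nav$capture_radius) {
      sim$outcome <- "captured"
      sim$captured_target <- selected
      action <- "accept"
    }
  }

  # pose: the emission position with the headings as updated by this
  # epoch's echo (what the per-epoch frames display)
  sim$records[[length(sim$records) + 1]] <- list(
    epoch = sim$bat$epoch_index, x = prev[1], y = prev[2],
    flight_deg = vec_to_heading(bat$flight_heading),
    beam_deg = vec_to_heading(bat$beam_heading),
    selected = if (is.na(selected)) NA_character_ else selected,
    action = action, delay_est_s = delay, azimuth_deg = az,
    glint_dt_est_s = gdt, confidence = conf)
  sim$bat <- bat
  sim$rng <- get(".Random.seed", envir = globalenv())
  sim
}

records_df <- function(records) {
  if (!length(records)) return(data.frame(
    epoch = integer(0), x = numeric(0), y = numeric(0),
    flight_deg = numeric(0), beam_deg = numeric(0),
    selected = character(0), action = character(0), delay_est_s = numeric(0),
    azimuth_deg = numeric(0), glint_dt_est_s = numeric(0),
    confidence = numeric(0)))
  do.call(rbind, lapply(records, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Run a full scene search
#'
#' Loops [run_epoch()] until the desired target is accepted and reached
#' within the capture radius (`"captured"`), every target has been rejected
#' (`"exhausted"`), or `max_epochs` is hit.
#'
#' @param scene a `scat_scene`.
#' @param config a [batnav_config()].
#' @param seed integer; seeds the per-run echo-noise stream.
#' @param max_epochs hard epoch limit.
#' @return an object of class `batnav_result`: `records` (one data-frame row
#'   per epoch), `outcome`, `captured_target`, `epochs_per_target` (the
#'   epochs-per-target attribution table), plus the scene, config and seed.
#' @export
run_search <- function(scene, config = batnav_config(), seed = 1,
                       max_epochs = 5000) {
  sim <- batnav_sim(scene, config, seed)
  while (is.na(sim$outcome) && length(sim$records) < max_epochs)
    sim <- run_epoch(sim)
  outcome <- if (is.na(sim$outcome)) "max_epochs" else sim$outcome
  rec <- records_df(sim$records)
  res <- structure(list(records = rec, outcome = outcome,
                        captured_target = sim$captured_target,
                        epochs_per_target = NULL, scene = scene,
                        config = config, seed = seed),
                   class = "batnav_result")
  res$epochs_per_target <- epochs_metric(res)
  res
}

#' Epochs-per-target attribution table
#'
#' Each epoch is attributed to the target selected at that epoch (scanning
#' epochs with no engaged target are pooled under `"(scan)"`); the counts
#' sum to the total number of epochs.  The verdict per target is the last
#' classification decision it received.
#'
#' @param result a [run_search()] result.
#' @return data frame with columns `target`, `epochs`, `verdict`, `order`.
#' @export
epochs_metric <- function(result) {
  rec <- result$records
  tgt <- ifelse(is.na(rec$selected), "(scan)", rec$selected)
  first_seen <- tapply(seq_along(tgt), tgt, min)
  ids <- names(sort(first_seen))
  verdict <- vapply(ids, function(id) {
    acts <- rec$action[tgt == id]
    if (any(acts == "accept")) "accept"
    else if (any(acts == "reject")) "reject"
    else if (id == "(scan)") "scan"
    else "incomplete"
  }, character(1))
  data.frame(target = ids,
             epochs = as.integer(table(tgt)[ids]),
             verdict = verdict,
             order = seq_along(ids), row.names = NULL)
}

#' @export
print.batnav_result <- function(x, ...) {
  cat(sprintf("<batnav_result> outcome: %s after %d epochs\n", x$outcome,
              nrow(x$records)))
  if (!is.na(x$captured_target))
    cat("  captured target:", x$captured_target, "\n")
  invisible(x)
}

#' @export
summary.batnav_result <- function(object, ...) {
  print(object)
  cat("epochs per target:\n")
  print(object$epochs_per_target, row.names = FALSE)
  invisible(object)
}

#' Plot the flight-track history of a search
#'
#' Flight path in blue with per-epoch beam-aim ticks in black; targets as
#' dots (the desired-spacing target in red), start at the origin of the
#' track.
#'
#' @param x a `batnav_result`.
#' @param beam_len length of the beam ticks, metres.
#' @param ... passed to [graphics::plot()].
#' @export
plot.batnav_result <- function(x, beam_len = 0.15, ...) {
  rec <- x$records
  pos <- t(vapply(x$scene$targets, `[[`, numeric(2), "position"))
  des <- desired_target_index(x$scene)
  start <- x$scene$bat_init$position
  xs <- c(start[1], rec$x); ys <- c(start[2], rec$y)
  graphics::plot(range(c(xs, pos[, 1])), range(c(ys, pos[, 2])),
                 type = "n", xlab = "crossrange (m)", ylab = "range (m)",
                 asp = 1, ...)
  graphics::points(pos[, 1], pos[, 2], pch = 19, col = "grey40")
  graphics::points(pos[des, 1], pos[des, 2], pch = 19, col = "red",
                   cex = 1.3)
  graphics::lines(xs, ys, col = "blue", lwd = 2)
  graphics::points(rec$x, rec$y, pch = 16, cex = 0.4)
  bd <- deg2rad(rec$beam_deg)
  graphics::segments(rec$x, rec$y, rec$x - beam_len * sin(bd),
                     rec$y + beam_len * cos(bd), col = "black")
  invisible(x)
}

#' Export a run to disk
#'
#' Writes the per-epoch track as CSV, a JSON run summary (outcome, captured
#' target, epochs-per-target table), and optionally one PNG frame per epoch
#' showing the flight path, beam aim and targets.
#'
#' @param result a [run_search()] result.
#' @param out_dir output directory (created if missing).
#' @param frames logical; write per-epoch PNG frames.
#' @return invisibly, the paths written.
#' @export
export_run <- function(result, out_dir, frames = FALSE) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory ", out_dir)
  track_path <- file.path(out_dir, "track.csv")
  utils::write.csv(result$records, track_path, row.names = FALSE)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(outcome = result$outcome,
                            captured_target = result$captured_target,
                            seed = result$seed,
                            n_epochs = nrow(result$records),
                            epochs_per_target = result$epochs_per_target),
                       summary_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths <- c(track_path, summary_path)
  if (frames) {
    fdir <- file.path(out_dir, "frames")
    dir.create(fdir, showWarnings = FALSE)
    for (i in seq_len(nrow(result$records))) {
      fp <- file.path(fdir, sprintf("epoch_%04d.png", i - 1))
      grDevices::png(fp, width = 600, height = 600)
      sub <- result
      sub$records <- result$records[seq_len(i), , drop = FALSE]
      plot(sub, main = sprintf("epoch %d", i - 1))
      grDevices::dev.off()
      paths <- c(paths, fp)
    }
  }
  invisible(paths)
}
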