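test_that("binaural azimuth is the arcsine of the normalised delay difference", {
  p <- nav_params()
  expect_equal(as.numeric(binaural_azimuth(5e-3, 5e-3, p)), 0)
  itd <- 0.014 * sin(pi / 6) / 340      # 30 deg to the right
  expect_equal(as.numeric(binaural_azimuth(itd, 0, p)), 30, tolerance = 1e-6)
  expect_equal(as.numeric(binaural_azimuth(0, itd, p)), -30,
               tolerance = 1e-6)
  over <- binaural_azimuth(1e-4, 0, p)  # beyond the physical maximum
  expect_equal(as.numeric(over), 90)
  expect_true(attr(over, "clamped"))
})

test_that("the nearest unrejected candidate is engaged, ties to the lower id", {
  cand <- data.frame(id = c("b", "a", "c"), delay = c(9e-3, 6e-3, 12e-3))
  expect_equal(select_nearest(cand)$id, "a")
  expect_equal(select_nearest(cand, rejected = "a")$id, "b")
  tie <- data.frame(id = c("d", "c"), delay = c(5e-3, 5e-3))
  expect_equal(select_nearest(tie)$id, "c")
  expect_null(select_nearest(cand, rejected = c("a", "b", "c")))
  expect_null(select_nearest(cand[0, ]))
})

test_that("beam aim turns toward the azimuth estimate, clamped at the limit", {
  p <- nav_params(max_beam_turn = 30, max_flight_turn = 10)
  s <- bat_state()
  expect_equal(update_beam_aim(s, 0, p)$beam_heading, c(0, 1))
  s20 <- update_beam_aim(s, 20, p)
  expect_equal(batnav:::signed_angle(s$beam_heading, s20$beam_heading), -20)
  s50 <- update_beam_aim(s, 50, p)
  expect_equal(batnav:::signed_angle(s$beam_heading, s50$beam_heading), -30)
})

test_that("flight turns toward the beam at its own limit, then advances", {
  p <- nav_params(max_flight_turn = 10, speed = 0.1)
  s <- bat_state(beam_heading = c(1, 0))  # beam 90 deg right of flight
  s2 <- update_flight(s, p)
  expect_equal(abs(batnav:::signed_angle(s$flight_heading,
                                         s2$flight_heading)), 10)
  expect_equal(s2$epoch_index, 1L)
  expect_equal(batnav:::vec_norm(s2$position - s$position), 0.1)

  aligned <- bat_state()
  a2 <- update_flight(aligned, p)
  expect_equal(a2$position, c(0, 0.1))
  expect_equal(a2$flight_heading, c(0, 1))
})

test_that("the flight-beam gap closes monotonically on a fixed target", {
  p <- nav_params()
  s <- bat_state(position = c(0, 0), flight_heading = c(0, 1))
  target <- c(3, 8)  # far, well off axis
  gaps <- numeric(12)
  for (i in 1:12) {
    az <- -batnav:::signed_angle(s$beam_heading, target - s$position)
    s <- update_beam_aim(s, az, p)
    gaps[i] <- abs(batnav:::signed_angle(s$flight_heading, s$beam_heading))
    s <- update_flight(s, p)
  }
  expect_true(all(diff(gaps) <= 1e-9))
})

test_that("classification accepts only the desired spacing inside the gate", {
  p <- nav_params(classify_azimuth_gate = 5)
  est <- function(gdt, sec = numeric(0), delay = 5e-3)
    list(overall_delay = delay, glint_dt = gdt, secondary_delays = sec)
  expect_equal(classify_target(est(100e-6), 1, p), "accept")
  expect_equal(classify_target(est(110e-6), 1, p), "accept")  # inside 20 us
  expect_equal(classify_target(est(300e-6), 1, p), "reject")
  expect_equal(classify_target(est(100e-6), 15, p), "approach")
  expect_equal(classify_target(est(NA, sec = c(5e-3, 6e-3)), 1, p), "reject")
  expect_equal(classify_target(est(NA), 1, p), "lost")
  expect_equal(classify_target(NULL, 1, p), "lost")
})

test_that("the receiver-classifier chain never accepts a distractor spacing", {
  p <- nav_params()
  for (dt in c(30, 50, 200, 300, 1000, 2000) * 1e-6) {
    e <- make_glint_echo(c(6e-3, 6e-3 + dt))
    est <- analyze_echo(e, bn_ref)
    expect_false(identical(classify_target(est, 0, p), "accept"),
                 label = sprintf("dt = %.0f us accepted", dt * 1e6))
  }
  # and the desired spacing is accepted under the same conditions
  e <- make_glint_echo(c(6e-3, 6.1e-3))
  expect_equal(classify_target(analyze_echo(e, bn_ref), 0, p), "accept")
})

test_that("paired binaural disparity recovers a sub-sample delay difference", {
  sc <- build_scene(list(list(position = 1.8 * c(sin(pi / 9), cos(pi / 9)),
                              spacing_s = 100e-6)))
  es <- synthesize_binaural_echoes(sc, sc$bat_init, bn_broadcast,
                                   snr_db = Inf)
  estL <- analyze_echo(es$left, bn_ref)
  estR <- analyze_echo(es$right, bn_ref)
  itd <- binaural_delay_difference(estL, estR, estL$overall_delay)
  truth <- es$truth$delay_left - es$truth$delay_right
  expect_lt(abs(itd - truth), 2e-6)
})
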