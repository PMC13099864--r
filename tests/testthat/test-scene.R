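test_that("glint spacings given as end-on delays convert through the sound speed", {
  sc <- build_scene(list(list(position = c(0, 1.5), spacing_s = 100e-6)))
  expect_equal(sc$targets[[1]]$glint_spacing, 0.017)

  sc2 <- build_scene(list(list(position = c(0, 1), spacing_s = 1)),
                     sound_speed = 2)
  expect_equal(sc2$targets[[1]]$glint_spacing, 1)

  sc3 <- build_scene(list(list(position = c(0, 1), spacing_s = 30e-6),
                          list(position = c(1, 1), spacing_s = 1000e-6)))
  expect_equal(sc3$targets[[1]]$glint_spacing, 0.0051)
  expect_equal(sc3$targets[[2]]$glint_spacing, 0.17)
})

test_that("scene validation rejects degenerate inputs", {
  expect_error(build_scene(list()), "at least one")
  expect_error(build_scene(list(list(position = c(0, 1), spacing_s = 0))),
               "spacing")
  expect_error(build_scene(list(list(position = c(0, 1), spacing_s = 1e-4),
                                list(position = c(0, 1), spacing_s = 2e-4))),
               "distinct")
})

test_that("projected glint delay follows the aspect-angle geometry", {
  # end-on view: the observer sits on the glint axis, full delay recovered
  tg <- scat_target("a", c(0, 1.5), 0.017, glint_axis = c(0, 1))
  expect_equal(projected_glint_delay(tg, c(0, 100)), 100e-6)
  # broadside: both glints equidistant, zero is a valid value
  expect_equal(projected_glint_delay(tg, c(100, 1.5)), 0)
  # oblique 60 deg between axis and line of sight, far field ~ |cos|
  tg60 <- scat_target("b", c(0, 0), 0.017,
                      glint_axis = c(sin(pi / 3), cos(pi / 3)))
  d <- projected_glint_delay(tg60, c(0, 100))
  expect_equal(d, 50e-6, tolerance = 0.01)
  # exchanging the two glints (axis -> -axis) changes nothing
  tg_flip <- scat_target("c", c(0, 0), 0.017,
                         glint_axis = -c(sin(pi / 3), cos(pi / 3)))
  expect_equal(projected_glint_delay(tg_flip, c(0, 100)), d)
  # observer-facing targets are end-on from anywhere
  tgf <- scat_target("d", c(1, 2), 0.017)
  expect_equal(projected_glint_delay(tgf, c(-3, 0.5)), 100e-6)
})

test_that("far-field cosine law emerges from the exact two-point formula", {
  tg <- scat_target("a", c(0, 0), 0.017,
                    glint_axis = heading_vec <- c(0, 1))
  for (theta in c(10, 35, 70)) {
    obs <- 5 * c(sin(theta * pi / 180), cos(theta * pi / 180))  # 5 m >> 17 mm
    exact <- projected_glint_delay(tg, obs)
    farfield <- (2 * 0.017 / 340) * abs(cos(theta * pi / 180))
    expect_equal(exact, farfield, tolerance = 1e-3)
  }
})

test_that("presets have the stated target counts and exactly one desired target", {
  counts <- c(single = 1, five = 5, eight = 8, twenty = 20, grid90 = 90)
  for (nm in names(counts)) {
    sc <- preset_scene(nm)
    expect_length(sc$targets, counts[[nm]])
    expect_length(desired_target_index(sc), 1)
  }
  sc <- preset_scene("single")
  expect_equal(sc$targets[[1]]$position, c(0, 1.5))
  expect_equal(2 * sc$targets[[1]]$glint_spacing / sc$sound_speed, 100e-6)
  expect_error(preset_scene("nonesuch"), "single.*five.*eight")
})

test_that("random scenes are reproducible and always contain one desired target", {
  a <- random_scene(12, seed = 7)
  b <- random_scene(12, seed = 7)
  expect_identical(a, b)
  for (s in 1:20) {
    sc <- random_scene(8, seed = s)
    expect_length(desired_target_index(sc), 1)
    pos <- t(vapply(sc$targets, `[[`, numeric(2), "position"))
    expect_gte(min(dist(pos)), 0.4)
  }
  # the caller's RNG stream is not consumed
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(random_scene(5, seed = 3)); x2 <- runif(1)
  expect_identical(x1, x2)
  expect_error(random_scene(500, seed = 1, max_tries = 200), "could not place")
})

test_that("scene YAML files round-trip", {
  sc <- random_scene(6, seed = 4)
  sc$targets[[2]]$glint_axis <- c(0, 1)  # one fixed-axis target
  path <- tempfile(fileext = ".yaml")
  write_scene(sc, path)
  rt <- read_scene(path)
  expect_equal(length(rt$targets), length(sc$targets))
  for (i in seq_along(sc$targets)) {
    expect_equal(rt$targets[[i]]$position, sc$targets[[i]]$position)
    expect_equal(rt$targets[[i]]$glint_spacing, sc$targets[[i]]$glint_spacing)
    expect_equal(is.null(rt$targets[[i]]$glint_axis),
                 is.null(sc$targets[[i]]$glint_axis))
  }
  expect_equal(rt$bat_init$position, sc$bat_init$position)
  expect_equal(rt$sound_speed, sc$sound_speed)
  unlink(path)
})
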