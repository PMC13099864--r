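test_that("a single-target scene is approached and captured", {
  res <- run_search(preset_scene("single"), seed = 1)
  expect_equal(res$outcome, "captured")
  expect_equal(res$captured_target, "t01")
  m <- res$epochs_per_target
  expect_equal(nrow(m), 1)
  expect_equal(m$epochs, nrow(res$records))
  expect_equal(m$verdict, "accept")
})

test_that("the five-target scene ends on the desired target, rejecting on the way", {
  sc <- preset_scene("five")
  res <- run_search(sc, seed = 2)
  expect_equal(res$outcome, "captured")
  expect_equal(res$captured_target, "t05")
  expect_equal(scene_spacing_s(sc, res$captured_target), 100e-6)
  m <- res$epochs_per_target
  approached <- m$target[!(m$target %in% c("t05", "(scan)"))]
  expect_true(all(m$verdict[m$target %in% approached] == "reject"))
  # attribution conserves the epoch count
  expect_equal(sum(m$epochs), nrow(res$records))
  # greedy start: the first engaged target is the nearest to the origin
  dists <- vapply(sc$targets, function(t) sum(t$position^2), numeric(1))
  nearest <- sc$targets[[which.min(dists)]]$id
  first_sel <- res$records$selected[!is.na(res$records$selected)][1]
  expect_equal(first_sel, nearest)
})

test_that("identical scene, config and seed give identical runs", {
  sc <- preset_scene("five")
  r1 <- run_search(sc, seed = 11)
  r2 <- run_search(sc, seed = 11)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$outcome, r2$outcome)
})

test_that("a scene without the desired spacing is exhausted with no accepts", {
  sc <- build_scene(list(list(position = c(-0.4, 1.2), spacing_s = 300e-6),
                         list(position = c(0.6, 1.6), spacing_s = 1000e-6)))
  res <- run_search(sc, seed = 5, max_epochs = 400)
  expect_equal(res$outcome, "exhausted")
  expect_true(is.na(res$captured_target))
  expect_false(any(res$records$action == "accept"))
})

test_that("run_epoch refuses once the scene is resolved", {
  sim <- batnav_sim(preset_scene("single"), seed = 1)
  while (is.na(sim$outcome)) sim <- run_epoch(sim)
  expect_error(run_epoch(sim), "resolved")
})

test_that("exported runs round-trip through the track CSV and JSON summary", {
  res <- run_search(preset_scene("single"), seed = 3)
  out <- file.path(tempdir(), "batnav-export-test")
  paths <- export_run(res, out)
  expect_true(all(file.exists(paths)))
  track <- utils::read.csv(file.path(out, "track.csv"))
  expect_equal(nrow(track), nrow(res$records))
  expect_equal(track$x, res$records$x)
  expect_equal(track$y, res$records$y)
  expect_equal(track$action, res$records$action)
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(js$outcome, res$outcome)
  expect_equal(js$n_epochs, nrow(res$records))
  unlink(out, recursive = TRUE)
})

test_that("per-epoch frames are written when enabled", {
  skip_if_not(capabilities("png"), "png device unavailable")
  res <- run_search(preset_scene("single"), seed = 3)
  out <- file.path(tempdir(), "batnav-frames-test")
  export_run(res, out, frames = TRUE)
  frames <- list.files(file.path(out, "frames"), pattern = "\\.png$")
  expect_length(frames, nrow(res$records))
  unlink(out, recursive = TRUE)
})

test_that("epochs to the first target grow with its distance from the start", {
  first_epochs <- dist0 <- numeric(0)
  for (s in 1:20) {
    sc <- random_scene(5, seed = 100 + s)
    res <- run_search(sc, seed = s, max_epochs = 600)
    m <- res$epochs_per_target
    m <- m[m$target != "(scan)", , drop = FALSE]
    first <- m$target[which.min(m$order)]
    tg <- Find(function(t) t$id == first, sc$targets)
    first_epochs <- c(first_epochs, m$epochs[m$order == min(m$order)])
    dist0 <- c(dist0, sqrt(sum(tg$position^2)))
  }
  fit <- stats::lm(first_epochs ~ dist0)
  expect_gt(stats::coef(fit)[["dist0"]], 0)
})
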