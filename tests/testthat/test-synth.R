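# Synthetic session generator: determinism, exact construction, closed-form
# ground truth, presets.

test_that("rendering is bit-identical for identical spec and seed", {
  spec <- scene_spec(duration = 6, motion_profile = rep(8, 19), seed = 42)
  a <- render_session(spec)
  b <- render_session(spec)
  for (i in seq_along(a$stream$frames))
    expect_identical(a$stream$frames[[i]]$pixels, b$stream$frames[[i]]$pixels)
  # a different seed changes the frames
  c <- render_session(scene_spec(duration = 6, motion_profile = rep(8, 19),
                                 seed = 43))
  expect_false(identical(a$stream$frames[[5]]$pixels,
                         c$stream$frames[[5]]$pixels))
})

test_that("zero motion and no blobs give zero coverage and full visualization", {
  spec <- scene_spec(duration = 6, seed = 1)   # profile defaults to zeros
  s <- render_session(spec)
  sc <- score_session(s$stream, s$annotation)
  expect_true(all(sc$traces$motion$samples$coverage == 0))
  expect_equal(sc$visualization, 100)
  expect_equal(sc$fine_movement, 0)   # static is below the band
})

test_that("commanded change fractions are realized exactly", {
  fracs <- c(1, 5, 10, 10, 25, 60, 0, 10, 33, 2, 18, 7, 50, 10, 4, 9, 11, 3, 6)
  spec <- scene_spec(duration = 6, motion_profile = fracs, seed = 7)
  s <- render_session(spec)
  tr <- fine_movement(s$stream, motion_config())
  n_px <- spec$width * spec$height
  expect_equal(tr$samples$coverage, 100 * round(fracs * n_px / 100) / n_px)
  expect_equal(tr$samples$coverage, s$ground_truth$expected_coverage)
  expect_true(all(abs(tr$samples$coverage - fracs) <= 0.5))
})

test_that("a blob at half the half-diagonal scores its area times 2/3", {
  blob <- data.frame(start_s = 0.9, end_s = 3.0, area_percent = 5,
                     center_frac = 0.5, angle_deg = NA_real_)
  spec <- scene_spec(duration = 6, motion_profile = rep(10, 19),
                     blob_events = blob, seed = 9)
  s <- render_session(spec)
  tr <- visualization(s$stream, exposure_config())
  active <- tr$samples$weighted_area[4:10]   # blocks 3..9
  expect_true(all(abs(active - 5 * 2/3) <= 0.5))
  inactive <- tr$samples$weighted_area[c(1:3, 12:20)]
  expect_true(all(inactive == 0))
  expect_true(max(abs(tr$samples$weighted_area - s$ground_truth$expected_wa)) <= 0.5)
})

test_that("infeasible scenes are rejected", {
  expect_error(scene_spec(duration = 6, motion_profile = rep(120, 19)),
               class = "endoskill_schema_error")
  expect_error(scene_spec(duration = 6, motion_profile = rep(5, 7)),
               class = "endoskill_schema_error")  # wrong profile length
  # a blob appearing during a static interval changes more pixels than commanded
  blob <- data.frame(start_s = 0.9, end_s = 3.0, area_percent = 10,
                     center_frac = 0.2, angle_deg = NA_real_)
  spec <- scene_spec(duration = 6, motion_profile = rep(0, 19),
                     blob_events = blob, seed = 2)
  expect_error(render_session(spec), class = "endoskill_schema_error")
})

test_that("ground truth is computed from the scene alone", {
  spec <- profile_presets("professional", trial = 4, seed = 11)
  gt_standalone <- ground_truth(spec, run_config())
  s <- render_session(spec)
  expect_identical(gt_standalone, s$ground_truth)
})

test_that("preset scorecards separate the two profiles as constructed", {
  prof <- render_session(profile_presets("professional", trial = 1, seed = 5))
  tra <- render_session(profile_presets("trainee", trial = 1, seed = 5))
  sc_p <- score_session(prof$stream, prof$annotation)
  sc_t <- score_session(tra$stream, tra$annotation)
  expect_gt(sc_p$fine_movement, sc_t$fine_movement)
  expect_lt(sc_t$target_detection, 100)
  expect_equal(sc_p$target_detection, 100)
  expect_gt(sc_p$efficiency, sc_t$efficiency)
  # reproducible: same preset + seed give identical scorecards
  tra2 <- render_session(profile_presets("trainee", trial = 1, seed = 5))
  expect_identical(scorecard_table(score_session(tra2$stream, tra2$annotation)),
                   scorecard_table(sc_t))
})

test_that("scored sessions reproduce the closed-form ground truth", {
  for (seed in c(2, 3)) {
    spec <- profile_presets("trainee", trial = seed, seed = seed)
    s <- render_session(spec)
    sc <- score_session(s$stream, s$annotation)
    gt <- s$ground_truth$expected_scores
    expect_equal(sc$target_detection, gt$target_detection)
    expect_equal(sc$fine_movement, gt$fine_movement)
    expect_equal(sc$visualization, gt$visualization, tolerance = 0.01)
    expect_equal(sc$efficiency, gt$efficiency)
  }
})

test_that("written sessions are complete and re-scorable from disk", {
  dir <- file.path(tempdir(), "synth_session")
  on.exit(unlink(dir, recursive = TRUE))
  spec <- scene_spec(duration = 3, motion_profile = rep(10, 9),
                     stone_events = data.frame(target_id = "stone_1",
                                               time_s = 1.2),
                     session_time_min = 4, seed = 17)
  s <- render_session(spec)
  write_session(s, dir)
  expect_true(file.exists(file.path(dir, "annotation.json")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  st <- open_stream(file.path(dir, "frames"), fps = spec$fps)
  expect_equal(st$meta$frame_count, s$stream$meta$frame_count)
  # PNG round trip preserves the rendered pixels exactly
  expect_equal(st$frames[[10]]$pixels, s$stream$frames[[10]]$pixels)
  sc_disk <- score_session(st, read_annotation(file.path(dir, "annotation.json")))
  sc_mem <- score_session(s$stream, s$annotation)
  expect_equal(sc_disk$fine_movement, sc_mem$fine_movement)
  expect_equal(sc_disk$visualization, sc_mem$visualization)
})
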