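# Fine Movement: differencing, binarization, coverage, band score,
# session aggregation.

test_that("difference image is the per-pixel absolute difference", {
  a <- frame_sample(matrix(120, 4, 4))
  b <- frame_sample(matrix(70, 4, 4))
  expect_equal(difference_image(a, b), matrix(50, 4, 4))
  expect_equal(difference_image(a, a), matrix(0, 4, 4))
  set.seed(11)
  m1 <- matrix(sample(0:255, 64, TRUE), 8, 8)
  m2 <- matrix(sample(0:255, 64, TRUE), 8, 8)
  f1 <- frame_sample(m1); f2 <- frame_sample(m2)
  expect_equal(difference_image(f1, f2), brute_diff(m1, m2))
  # symmetry
  expect_equal(difference_image(f1, f2), difference_image(f2, f1))
  expect_error(difference_image(f1, frame_sample(matrix(0, 3, 3))),
               class = "endoskill_schema_error")
})

test_that("binarization is strict at the threshold", {
  expect_equal(binarize(matrix(51, 1, 1), 50)[1, 1], 1L)
  expect_equal(binarize(matrix(50, 1, 1), 50)[1, 1], 0L)
  expect_equal(binarize(matrix(0, 3, 3), 50), matrix(0L, 3, 3))
  set.seed(12)
  d <- matrix(sample(0:255, 100, TRUE), 10, 10)
  expect_equal(binarize(d, 50), brute_binarize(d, 50))
})

test_that("coverage is the percentage of set pixels", {
  expect_equal(coverage(matrix(0L, 5, 5)), 0)
  expect_equal(coverage(matrix(1L, 5, 5)), 100)
  m <- matrix(0L, 10, 10); m[sample.int(100, 37)] <- 1L
  expect_equal(coverage(m), 37)
  set.seed(13)
  m2 <- matrix(rbinom(144, 1, 0.3), 12, 12)
  expect_equal(coverage(m2), brute_coverage(m2))
})

test_that("per-pair score is 100 inside the band (inclusive) and 0 outside", {
  cfg <- motion_config(eps_low = 0.5, eps_high = 20)
  expect_equal(frame_score(10, cfg), 100)
  expect_equal(frame_score(0.5, cfg), 100)   # boundary inclusive
  expect_equal(frame_score(20, cfg), 100)    # boundary inclusive
  expect_equal(frame_score(0.2, cfg), 0)     # too slow
  expect_equal(frame_score(35, cfg), 0)      # too fast
  expect_equal(frame_score(c(0, 5, 25), cfg), c(0, 100, 0))
})

test_that("session score is the mean over all sampled pairs", {
  # all pairs in band -> 100; half in band -> 50
  st_in <- fraction_stream(rep(10, 8), seed = 21)
  tr_in <- fine_movement(st_in, motion_config())
  expect_equal(tr_in$session_score, 100)
  st_half <- fraction_stream(rep(c(10, 0), 4), seed = 22)
  tr_half <- fine_movement(st_half, motion_config())
  expect_equal(tr_half$session_score, 50)
  expect_equal(nrow(tr_half$samples), 8)
  expect_true(all(tr_half$samples$score %in% c(0, 100)))
  # too-short stream is a computation error
  expect_error(fine_movement(random_stream(2, fps = 10), motion_config()),
               class = "endoskill_compute_error")
})

test_that("measured coverage equals the commanded change fraction", {
  fracs <- c(0, 3, 10, 25, 50)
  st <- fraction_stream(fracs, nr = 20, nc = 20, seed = 23)
  tr <- fine_movement(st, motion_config())
  expect_equal(tr$samples$coverage, 100 * round(fracs * 400 / 100) / 400)
})

test_that("full motion pipeline matches a nested-loop recomputation", {
  st <- random_stream(14, nr = 8, nc = 8, fps = 10, seed = 31)
  cfg <- motion_config()
  tr <- fine_movement(st, cfg)
  pairs <- sample_pairs(st, cfg$interval)
  brute_scores <- vapply(pairs, function(p) {
    cov <- brute_coverage(brute_binarize(
      brute_diff(p$current$pixels, p$previous$pixels), cfg$diff_threshold))
    if (cov >= cfg$eps_low && cov <= cfg$eps_high) 100 else 0
  }, numeric(1))
  expect_identical(tr$samples$score, brute_scores)
  expect_identical(tr$session_score, mean(brute_scores))
})

test_that("coverage never decreases as more pixels change", {
  set.seed(41)
  base <- matrix(sample(40:140, 400, TRUE), 20, 20)
  prev <- frame_sample(base)
  changed_order <- sample.int(400)
  last_cov <- -1
  for (k in c(0, 10, 50, 120, 300, 400)) {
    cur <- base
    idx <- changed_order[seq_len(k)]
    cur[idx] <- ifelse(cur[idx] <= 127, cur[idx] + 90, cur[idx] - 90)
    cov <- coverage(binarize(difference_image(frame_sample(cur), prev), 50))
    expect_gte(cov, last_cov)
    last_cov <- cov
  }
})

test_that("session score is invariant to resolution at fixed change fraction", {
  fracs <- c(2, 8, 15, 30, 0, 12)
  cfg <- motion_config()
  s_small <- fine_movement(fraction_stream(fracs, nr = 20, nc = 20, seed = 5), cfg)
  s_large <- fine_movement(fraction_stream(fracs, nr = 40, nc = 40, seed = 6), cfg)
  expect_equal(s_small$session_score, s_large$session_score)
})

test_that("motion traces serialize to CSV and JSON", {
  st <- fraction_stream(rep(10, 4), seed = 51)
  tr <- fine_movement(st, motion_config())
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  on.exit(unlink(c(csv, js)))
  write_trace(tr, csv)
  back <- read.csv(csv)
  expect_equal(back$coverage, tr$samples$coverage)
  write_trace(tr, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$session_score, tr$session_score)
})
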