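# Visualization: saturation masking, denoising/blob measurement, radial
# weighting, per-frame and session scores.

test_that("over-exposure mask is strict at the saturation threshold", {
  cfg <- exposure_config()
  f <- matrix(c(246, 245, 244, 255), 2, 2)
  expect_equal(overexposure_mask(f, cfg), matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(overexposure_mask(matrix(100, 3, 3), cfg), matrix(0L, 3, 3))
  set.seed(61)
  m <- matrix(sample(200:255, 100, TRUE), 10, 10)
  expect_equal(overexposure_mask(m, cfg),
               matrix(as.integer(m > 245), 10, 10))
})

test_that("blob extraction finds solid squares with analytic centroids", {
  cfg <- exposure_config()
  mask <- matrix(0L, 100, 100)
  mask[48:52, 48:52] <- 1L  # 5x5 solid square
  blobs <- denoise_and_blobs(mask, cfg)
  expect_equal(nrow(blobs), 1)
  expect_equal(blobs$area_percent, 0.25)
  expect_equal(blobs$x, 50); expect_equal(blobs$y, 50)
  # two isolated squares -> two blobs
  mask[10:14, 10:14] <- 1L
  expect_equal(nrow(denoise_and_blobs(mask, cfg)), 2)
})

test_that("denoising removes scattered single pixels", {
  cfg <- exposure_config()
  set.seed(62)
  mask <- matrix(0L, 80, 80)
  # isolated pixels on a sparse grid (never adjacent)
  sites <- expand.grid(r = seq(5, 75, by = 5), c = seq(5, 75, by = 5))
  keep <- sample.int(nrow(sites), 30)
  mask[cbind(sites$r[keep], sites$c[keep])] <- 1L
  expect_equal(nrow(denoise_and_blobs(mask, cfg)), 0)
})

test_that("components are 8-connected", {
  cfg <- exposure_config(opening_size = 0, min_blob_area = 0)
  mask <- matrix(0L, 10, 10)
  mask[2, 2] <- 1L; mask[3, 3] <- 1L  # touch only diagonally
  expect_equal(nrow(denoise_and_blobs(mask, cfg)), 1)
  mask2 <- matrix(0L, 10, 10)
  mask2[2, 2] <- 1L; mask2[2, 4] <- 1L  # separated by a gap
  expect_equal(nrow(denoise_and_blobs(mask2, cfg)), 2)
})

test_that("radial weights take the printed band values", {
  cfg <- exposure_config()
  r <- 120
  expect_equal(weight_for_distance(0, r, cfg), 1)
  expect_equal(weight_for_distance(0.5 * r, r, cfg), 2/3)
  expect_equal(weight_for_distance(0.9 * r, r, cfg), 1/3)
  # band boundaries: d <= r/3 -> 1; d >= 2r/3 -> 1/3
  expect_equal(weight_for_distance(r / 3, r, cfg), 1)
  expect_equal(weight_for_distance(2 * r / 3, r, cfg), 1/3)
  expect_equal(weight_for_distance(r, r, cfg), 1/3)
  expect_error(weight_for_distance(1.2 * r, r, cfg),
               class = "endoskill_schema_error")
})

test_that("frame exposure takes the maximum weighted blob", {
  cfg <- exposure_config()
  # no saturation -> 0
  expect_equal(frame_exposure(matrix(100, 50, 50), cfg), 0)
  # one central blob of 9%: 30x30 in 100x100, w = 1
  f1 <- frame_with_rects(100, 100, list(list(rows = 36:65, cols = 36:65)))
  expect_equal(frame_exposure(f1, cfg), 9)
  # central 3% vs far-corner 12% in a 100x200 frame:
  # corner centroid sits beyond 2r/3, so max(1 * 3, 1/3 * 12) = 4
  f2 <- frame_with_rects(100, 200, list(
    list(rows = 41:60, cols = 86:115),   # 600 px = 3%, centroid at centre
    list(rows = 1:48, cols = 1:50)))     # 2400 px = 12%, corner
  expect_equal(frame_exposure(f2, cfg), 4)
})

test_that("frame exposure matches the flood-fill oracle on random masks", {
  cfg <- exposure_config(opening_size = 0, min_blob_area = 0)
  set.seed(63)
  for (rep in 1:25) {
    nr <- sample(6:14, 1); nc <- sample(6:14, 1)
    mask <- matrix(rbinom(nr * nc, 1, runif(1, 0.1, 0.5)), nr, nc)
    frame <- matrix(100, nr, nc)
    frame[mask == 1] <- 250
    expect_equal(frame_exposure(frame, cfg), brute_max_weighted_area(mask))
  }
})

test_that("session Visualization follows the closed form and is bounded", {
  cfg <- exposure_config()
  # no over-exposure anywhere -> 100
  clean <- frame_stream(replicate(12, matrix(120, 40, 40), simplify = FALSE),
                        fps = 10)
  expect_equal(visualization(clean, cfg)$session_score, 100)
  # constant central 10% blob on every frame -> 90
  f <- frame_with_rects(100, 200, list(list(rows = 31:70, cols = 76:125)))
  st <- frame_stream(replicate(12, f, simplify = FALSE), fps = 10)
  tr <- visualization(st, cfg)
  expect_equal(tr$session_score, 90)
  expect_true(all(tr$samples$weighted_area == 10))
  # fully saturated frames stay within [0, 100]
  sat <- frame_stream(replicate(6, matrix(255, 30, 30), simplify = FALSE),
                      fps = 10)
  sc <- visualization(sat, cfg)$session_score
  expect_gte(sc, 0); expect_lte(sc, 100)
})

test_that("moving a blob within an annulus leaves wA unchanged; moving it inward never decreases wA", {
  cfg <- exposure_config()
  nr <- 100; nc <- 200
  place <- function(row0, col0)
    frame_with_rects(nr, nc, list(list(rows = row0:(row0 + 19),
                                       cols = col0:(col0 + 19))))
  # r = sqrt(100^2 + 200^2)/2 = 111.8; blob 20x20 at distances inside one band
  wa_center <- frame_exposure(place(41, 91), cfg)      # d ~ 0, band 1
  wa_center2 <- frame_exposure(place(45, 100), cfg)    # still band 1
  expect_equal(wa_center, wa_center2)
  wa_mid <- frame_exposure(place(41, 140), cfg)        # d ~ 50, band 2
  wa_out <- frame_exposure(place(5, 170), cfg)         # far corner, band 3
  expect_gte(wa_center, wa_mid)
  expect_gte(wa_mid, wa_out)
})

test_that("adding saturated pixels never increases the session score", {
  cfg <- exposure_config()
  set.seed(64)
  for (rep in 1:8) {
    nr <- 60; nc <- 80
    base <- matrix(120, nr, nc)
    # base saturation: one random solid rectangle
    r0 <- sample(1:40, 1); c0 <- sample(1:60, 1)
    base[r0:(r0 + sample(5:15, 1)), c0:(c0 + sample(5:15, 1))] <- 255
    st0 <- frame_stream(list(base), fps = 10)
    s0 <- visualization(st0, cfg)$session_score
    # add another saturated rectangle anywhere
    more <- base
    r1 <- sample(1:45, 1); c1 <- sample(1:65, 1)
    more[r1:(r1 + sample(4:12, 1)), c1:(c1 + sample(4:12, 1))] <- 255
    s1 <- visualization(frame_stream(list(more), fps = 10), cfg)$session_score
    expect_lte(s1, s0)
  }
})
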