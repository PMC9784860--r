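# Synthetic endoscopy generator.
#
# Sessions are rendered as piecewise-constant blocks of one sampling
# interval (0.3 s), so every sampled frame pair spans exactly one block
# transition. At each transition the renderer changes EXACTLY the commanded
# number of pixels by more than the motion threshold (scene-event toggles
# first, then randomly chosen background pixels to make up the count), which
# makes the expected coverage A_i sharp rather than statistical. Saturated
# blobs are sets of exactly round(area% * N / 100) pixels centred (by
# iterative correction) on a commanded point expressed as a fraction of the
# half-diagonal, so the ground-truth radial weight follows directly from the
# scene description. Ground truth is computed from the scene alone, never
# from the rendered frames.

BG_LOW <- 30       # background grayscale range; toggling +-60 keeps values
BG_HIGH <- 110     # in [30, 160], far below the 245 saturation threshold
VESSEL_VALUE <- 150
STONE_VALUE <- 220
TOGGLE_DELTA <- 60 # per-pixel change applied to "moving" pixels (> DTh = 50)
STONE_AREA_FRAC <- 0.003  # stone sprite, fraction of frame area

empty_blobs <- function()
  data.frame(start_s = numeric(0), end_s = numeric(0),
             area_percent = numeric(0), center_frac = numeric(0),
             angle_deg = numeric(0))

empty_stones <- function()
  data.frame(target_id = character(0), time_s = numeric(0))

#' Describe a synthetic endoscopy session
#'
#' @param width,height Frame size in pixels. Defaults 96 x 72.
#' @param fps Frames per second. Default 10 (the sampling interval must span
#'   a whole number of frames).
#' @param duration Session length in seconds; must be a whole number of
#'   0.3 s blocks. Default 30.
#' @param motion_profile Commanded changed-pixel fraction (percent of frame)
#'   for each block transition; length `duration / 0.3 - 1`. Default all 0.
#' @param blob_events data.frame of saturated-blob events: `start_s`,
#'   `end_s` (snapped to block boundaries), `area_percent`, `center_frac`
#'   (centroid position as a fraction of the half-diagonal) and optionally
#'   `angle_deg` (direction from frame centre; default toward the
#'   bottom-right corner, the only direction that reaches large fractions).
#' @param stone_events data.frame of target appearances: `target_id`,
#'   `time_s`. A stone sprite appears at its time and persists.
#' @param total_targets Calculi placed. Default 3.
#' @param session_time_min Task time T recorded in the annotation, minutes.
#'   Defaults to the rendered duration.
#' @param group,session_id,trial_index Annotation metadata.
#' @param interval Block length, seconds. Default 0.3.
#' @param seed Integer; identical spec + seed give bit-identical frames.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width = 96, height = 72, fps = 10, duration = 30,
                       motion_profile = NULL, blob_events = empty_blobs(),
                       stone_events = empty_stones(), total_targets = 3,
                       session_time_min = NULL,
                       group = c("professional", "trainee"),
                       session_id = "synthetic", trial_index = 1,
                       interval = 0.3, seed = 1L) {
  group <- match.arg(group)
  fpb <- round(interval * fps)
  if (abs(fpb - interval * fps) > 1e-9 || fpb < 1)
    abort_schema("`interval` must span a whole number of frames")
  frame_count <- round(duration * fps)
  if (frame_count %% fpb != 0)
    abort_schema("`duration` must be a whole number of sampling intervals")
  n_blocks <- frame_count %/% fpb
  if (n_blocks < 2) abort_schema("session must span at least two intervals")
  n_pairs <- n_blocks - 1L
  if (is.null(motion_profile)) motion_profile <- rep(0, n_pairs)
  if (length(motion_profile) != n_pairs)
    abort_schema(sprintf("`motion_profile` must have %d entries (one per block transition)",
                         n_pairs))
  if (any(!is.finite(motion_profile)) || any(motion_profile < 0) ||
      any(motion_profile > 100))
    abort_schema("motion fractions must be within [0, 100] percent")
  if (nrow(blob_events)) {
    need <- c("start_s", "end_s", "area_percent", "center_frac")
    if (!all(need %in% names(blob_events)))
      abort_schema("`blob_events` needs columns start_s, end_s, area_percent, center_frac")
    if (is.null(blob_events$angle_deg))
      blob_events$angle_deg <- rep(NA_real_, nrow(blob_events))
    if (any(blob_events$start_s < 0) || any(blob_events$end_s > duration) ||
        any(blob_events$end_s <= blob_events$start_s))
      abort_schema("blob event times must satisfy 0 <= start < end <= duration")
    if (any(blob_events$area_percent <= 0) || any(blob_events$area_percent > 100))
      abort_schema("blob areas must be in (0, 100] percent")
    if (any(blob_events$center_frac < 0) || any(blob_events$center_frac >= 1))
      abort_schema("blob center_frac must be in [0, 1)")
  }
  if (nrow(stone_events)) {
    if (!all(c("target_id", "time_s") %in% names(stone_events)))
      abort_schema("`stone_events` needs columns target_id, time_s")
    stone_events$target_id <- as.character(stone_events$target_id)
    if (anyDuplicated(stone_events$target_id))
      abort_schema("stone target_ids must be unique")
    if (any(stone_events$time_s < 0) || any(stone_events$time_s > duration))
      abort_schema("stone event times must lie within the session")
    if (nrow(stone_events) > total_targets)
      abort_schema("more stone events than placed targets")
  }
  structure(list(width = width, height = height, fps = fps,
                 duration = duration, interval = interval,
                 frames_per_block = fpb, n_blocks = n_blocks,
                 n_pairs = n_pairs, motion_profile = motion_profile,
                 blob_events = blob_events, stone_events = stone_events,
                 total_targets = as.integer(total_targets),
                 session_time_min = session_time_min %||% (duration / 60),
                 group = group, session_id = session_id,
                 trial_index = as.integer(trial_index),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

blob_blocks <- function(spec) {
  ev <- spec$blob_events
  if (nrow(ev) == 0L)
    return(cbind(start = integer(0), end = integer(0)))
  cbind(start = pmin(spec$n_blocks, round(ev$start_s / spec$interval)),
        end = pmin(spec$n_blocks, round(ev$end_s / spec$interval)))
}

stone_blocks <- function(spec) {
  ev <- spec$stone_events
  if (nrow(ev) == 0L) return(integer(0))
  pmin(spec$n_blocks - 1L, pmax(0L, round(ev$time_s / spec$interval)))
}

#' Closed-form ground truth for a synthetic scene
#'
#' Computes, from the scene description alone (never from rendered frames):
#' the expected coverage of every sampled pair, the expected weighted
#' over-exposed area of every sampled frame, and the four analytic session
#' scores under the given configuration.
#'
#' @param spec A [scene_spec()].
#' @param config A [run_config()].
#' @return List with `expected_coverage` (per pair), `expected_wa`
#'   (per sampled frame), and `expected_scores` (the four metrics plus
#'   duration).
#' @export
ground_truth <- function(spec, config = run_config()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(config, "run_config"))
  n_px <- spec$width * spec$height
  k_px <- round(spec$motion_profile * n_px / 100)
  expected_coverage <- 100 * k_px / n_px
  r <- sqrt(spec$width^2 + spec$height^2) / 2
  bb <- blob_blocks(spec)
  ev <- spec$blob_events
  expected_wa <- vapply(seq_len(spec$n_blocks) - 1L, function(b) {
    act <- which(bb[, "start"] <= b & b < bb[, "end"])
    if (!length(act)) return(0)
    max(weight_for_distance(ev$center_frac[act] * r, r, config$exposure) *
          ev$area_percent[act])
  }, numeric(1))
  fm <- mean(frame_score(expected_coverage, config$motion))
  vis <- min(100, max(0, (1 - mean(expected_wa) / 100) * 100))
  td <- 100 * nrow(spec$stone_events) / spec$total_targets
  dur <- duration_score(spec$session_time_min, config$efficiency)
  eff <- efficiency(td, dur)
  list(expected_coverage = expected_coverage, expected_wa = expected_wa,
       expected_scores = list(target_detection = td, fine_movement = fm,
                              visualization = vis, efficiency = eff,
                              duration = dur))
}

# Exactly k pixels centred on `target` (x, y): iteratively recentre the
# k-nearest set under a mildly elliptical metric until its centroid matches
# the commanded point (clipping at frame borders is compensated by pushing
# the centre outward). Returns linear pixel indices.
place_pixel_set <- function(width, height, k, target, aspect = 1.25,
                            tol = 0.3, max_iter = 25) {
  if (k < 1) abort_schema("pixel set must have at least one pixel")
  if (k > width * height) abort_schema("pixel set larger than the frame")
  xs <- rep(seq_len(width), each = height)
  ys <- rep(seq_len(height), times = width)
  cx <- target[1]; cy <- target[2]
  sel <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- (xs - cx)^2 + (aspect * (ys - cy))^2
    sel <- order(d2)[seq_len(k)]
    err <- c(target[1] - mean(xs[sel]), target[2] - mean(ys[sel]))
    if (max(abs(err)) < tol) break
    cx <- cx + err[1]; cy <- cy + err[2]
  }
  realized <- c(mean(xs[sel]), mean(ys[sel]))
  if (max(abs(realized - target)) > 1.0)
    abort_compute(sprintf(
      "cannot place a %d-pixel blob with centroid at (%.1f, %.1f); achieved (%.1f, %.1f)",
      k, target[1], target[2], realized[1], realized[2]))
  sel
}

draw_vessels <- function(bg, n_curves = 14, steps = 60) {
  h <- nrow(bg); w <- ncol(bg)
  for (v in seq_len(n_curves)) {
    x <- stats::runif(1, 1, w); y <- stats::runif(1, 1, h)
    ang <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(steps)) {
      ang <- ang + stats::rnorm(1, 0, 0.35)
      x <- x + cos(ang); y <- y + sin(ang)
      xi <- round(x); yi <- round(y)
      if (xi < 1 || xi > w || yi < 1 || yi > h) break
      bg[yi, xi] <- VESSEL_VALUE
    }
  }
  bg
}

toggle_pixels <- function(v) ifelse(v <= 100, v + TOGGLE_DELTA, v - TOGGLE_DELTA)

#' Render a synthetic session
#'
#' Produces the frame stream, the session annotation and the closed-form
#' [ground_truth()]. Rendering is deterministic in `spec$seed`. The renderer
#' verifies its own exactness: at every block transition the number of
#' pixels changed by more than the motion threshold must equal the commanded
#' count, and every blob's realized centroid must land in the same radial
#' weight band as commanded.
#'
#' @param spec A [scene_spec()].
#' @param config A [run_config()]; the motion threshold must be below the
#'   generator's per-pixel change magnitude (60 gray levels).
#' @return List of class `synthetic_session`: `stream`, `annotation`,
#'   `ground_truth`, `spec`.
#' @export
render_session <- function(spec, config = run_config()) {
  stopifnot(inherits(spec, "scene_spec"), inherits(config, "run_config"))
  dth <- config$motion$diff_threshold
  if (dth >= TOGGLE_DELTA)
    abort_schema(sprintf(
      "renderer changes pixels by %d gray levels; diff_threshold must be below that",
      TOGGLE_DELTA))
  w <- spec$width; h <- spec$height; n_px <- w * h
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  bg <- matrix(floor(stats::runif(n_px, BG_LOW, BG_HIGH + 1)), h, w)
  bg <- draw_vessels(bg)

  r <- sqrt(w^2 + h^2) / 2
  ox <- (w + 1) / 2; oy <- (h + 1) / 2

  ev <- spec$blob_events
  bb <- blob_blocks(spec)
  blob_px <- vector("list", nrow(ev))
  band_of <- function(d) weight_for_distance(d, r, config$exposure)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      ang <- ev$angle_deg[i]
      u <- if (is.na(ang)) c(w, h) / sqrt(w^2 + h^2)
      else c(cos(ang * pi / 180), sin(ang * pi / 180))
      target <- c(ox, oy) + ev$center_frac[i] * r * u
      k <- round(ev$area_percent[i] * n_px / 100)
      blob_px[[i]] <- place_pixel_set(w, h, k, target)
      xs <- ((blob_px[[i]] - 1L) %/% h) + 1L
      ys <- ((blob_px[[i]] - 1L) %% h) + 1L
      d_real <- sqrt((mean(xs) - ox)^2 + (mean(ys) - oy)^2)
      if (band_of(d_real) != band_of(ev$center_frac[i] * r))
        abort_compute(sprintf("blob %d realized centroid falls outside its commanded weight band", i))
    }
    # time-overlapping blobs must not share pixels or the ground truth is off
    for (i in seq_len(nrow(ev))) for (j in seq_len(nrow(ev))) {
      if (i < j && bb[i, "start"] < bb[j, "end"] && bb[j, "start"] < bb[i, "end"] &&
          length(intersect(blob_px[[i]], blob_px[[j]])))
        abort_schema("time-overlapping blob events share pixels")
    }
  }

  st <- spec$stone_events
  st_blocks <- stone_blocks(spec)
  stone_sites <- list(c(0.25 * w, 0.30 * h), c(0.75 * w, 0.30 * h),
                      c(0.20 * w, 0.75 * h))
  stone_px <- vector("list", nrow(st))
  if (nrow(st)) {
    k_stone <- max(9, round(STONE_AREA_FRAC * n_px))
    for (i in seq_len(nrow(st))) {
      site <- stone_sites[[((i - 1) %% length(stone_sites)) + 1]]
      stone_px[[i]] <- place_pixel_set(w, h, k_stone, site, aspect = 1)
    }
  }

  # linear indices for a pixel-index vector (pixels stored column-major h x w)
  compose <- function(b) {
    m <- bg
    if (nrow(st)) for (i in seq_len(nrow(st)))
      if (st_blocks[i] <= b) m[stone_px[[i]]] <- STONE_VALUE
    if (nrow(ev)) for (i in seq_len(nrow(ev)))
      if (bb[i, "start"] <= b && b < bb[i, "end"]) m[blob_px[[i]]] <- 255
    m
  }
  overlay_mask <- function(b) {
    keep <- logical(n_px)
    if (nrow(st)) for (i in seq_len(nrow(st)))
      if (st_blocks[i] <= b) keep[stone_px[[i]]] <- TRUE
    if (nrow(ev)) for (i in seq_len(nrow(ev)))
      if (bb[i, "start"] <= b && b < bb[i, "end"]) keep[blob_px[[i]]] <- TRUE
    keep
  }

  keyframes <- vector("list", spec$n_blocks)
  k_prev <- compose(0)
  keyframes[[1]] <- k_prev
  mask_prev <- overlay_mask(0)
  for (b in seq_len(spec$n_pairs)) {
    k_target <- round(spec$motion_profile[b] * n_px / 100)
    k0 <- compose(b)
    c_toggle <- sum(abs(k0 - k_prev) > dth)
    extra <- k_target - c_toggle
    if (extra < 0)
      abort_schema(sprintf(
        "transition %d: scene events change %d pixels but only %d are commanded",
        b, c_toggle, k_target))
    mask_b <- overlay_mask(b)
    if (extra > 0) {
      candidates <- which(!mask_prev & !mask_b)
      if (length(candidates) < extra)
        abort_schema(sprintf("transition %d: not enough background pixels", b))
      pick <- candidates[sample.int(length(candidates), extra)]
      bg[pick] <- toggle_pixels(bg[pick])
    }
    k_new <- compose(b)
    if (sum(abs(k_new - k_prev) > dth) != k_target)
      abort_compute(sprintf("transition %d: realized change count differs from commanded", b))
    keyframes[[b + 1L]] <- k_new
    k_prev <- k_new
    mask_prev <- mask_b
  }

  frames <- vector("list", spec$n_blocks * spec$frames_per_block)
  for (b in seq_len(spec$n_blocks))
    for (f in seq_len(spec$frames_per_block))
      frames[[(b - 1L) * spec$frames_per_block + f]] <- keyframes[[b]]
  stream <- frame_stream(frames, fps = spec$fps)
  stream$meta$source <- sprintf("<synthetic:%s seed %d>", spec$session_id, spec$seed)

  ann <- session_annotation(
    session_id = spec$session_id, group = spec$group,
    session_time_min = spec$session_time_min,
    detected = if (nrow(st))
      data.frame(target_id = st$target_id, time_s = st_blocks * spec$interval)
    else empty_stones(),
    total_targets = spec$total_targets, trial_index = spec$trial_index)

  structure(list(stream = stream, annotation = ann,
                 ground_truth = ground_truth(spec, config), spec = spec),
            class = "synthetic_session")
}

#' Preset synthetic sessions: professional vs trainee profiles
#'
#' The professional profile intubates continuously at an appropriate speed
#' (most transitions inside the coverage band), shows only rare small
#' central saturation, finds all three stones and finishes under the time
#' budget. The trainee profile alternates static and abrupt out-of-band
#' movement, shows frequent larger saturated blobs (wall contact), always
#' misses the inferior-calyx stone (the hard target behind the
#' infundibulopelvic angle) and sometimes a second, and exceeds the time
#' budget. Profile parameters are drawn per trial from the preset's own
#' distributions, so repeated trials vary like repeated sessions.
#'
#' @param kind `"professional"` or `"trainee"`.
#' @param trial Trial index (varies the draw).
#' @param seed Base seed; the spec seed is derived from `seed` and `trial`.
#' @return A [scene_spec()].
#' @export
profile_presets <- function(kind = c("professional", "trainee"),
                            trial = 1, seed = 1L) {
  kind <- match.arg(kind)
  seed_i <- (as.integer(seed) * 10000L + as.integer(trial) * 13L +
               if (kind == "trainee") 5003L else 0L) %% 2147483629L
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed_i)

  n_pairs <- 99L; interval <- 0.3
  if (kind == "professional") {
    p_in <- stats::runif(1, 0.84, 0.92)
    f <- ifelse(stats::runif(n_pairs) < p_in, stats::runif(n_pairs, 4, 12), 0)
    n_blob <- 2L
    areas <- stats::runif(n_blob, 0.8, 2)
    fracs <- stats::runif(n_blob, 0.05, 0.25)
    starts <- c(sample(5:35, 1), sample(55:80, 1))
    lens <- sample(8:15, n_blob, replace = TRUE)
    t_min <- min(4.95, max(3.5, stats::rnorm(1, 4.3, 0.35)))
    detected <- c("stone_1", "stone_2", "stone_3")
  } else {
    p_in <- stats::runif(1, 0.32, 0.48)
    state <- ifelse(stats::runif(n_pairs) < p_in, "in",
                    ifelse(stats::runif(n_pairs) < 0.5, "static", "abrupt"))
    f <- numeric(n_pairs)
    f[state == "in"] <- stats::runif(sum(state == "in"), 4, 12)
    f[state == "abrupt"] <- stats::runif(sum(state == "abrupt"), 26, 38)
    n_blob <- 5L
    band <- sample(c("central", "mid", "outer"), n_blob, replace = TRUE,
                   prob = c(0.3, 0.4, 0.3))
    areas <- ifelse(band == "central", stats::runif(n_blob, 8, 16),
                    ifelse(band == "mid", stats::runif(n_blob, 8, 14),
                           stats::runif(n_blob, 4, 6)))
    fracs <- ifelse(band == "central", stats::runif(n_blob, 0.05, 0.28),
                    ifelse(band == "mid", stats::runif(n_blob, 0.42, 0.58),
                           stats::runif(n_blob, 0.69, 0.72)))
    lens <- sample(8:13, n_blob, replace = TRUE)
    gaps <- sample(3:6, n_blob, replace = TRUE)
    starts <- integer(n_blob)
    pos <- sample(3:8, 1)
    for (i in seq_len(n_blob)) { starts[i] <- pos; pos <- pos + lens[i] + gaps[i] }
    keep <- starts + lens <= n_pairs - 1L
    starts <- starts[keep]; lens <- lens[keep]
    areas <- areas[keep]; fracs <- fracs[keep]; n_blob <- sum(keep)
    t_min <- max(12, min(19, stats::rnorm(1, 15.4, 1.5)))
    detected <- c("stone_1", if (stats::runif(1) > 0.35) "stone_2")
  }
  ends <- starts + lens
  # commanded motion at a toggle transition must cover the toggled blob
  # area; for the trainee, wall contact goes with abrupt (out-of-band)
  # movement, for the professional it stays a small in-band adjustment
  toggle_floor <- if (kind == "trainee") pmax(areas + 5, 26) else areas + 3
  for (i in seq_len(n_blob)) {
    f[starts[i]] <- max(f[starts[i]], toggle_floor[i])
    if (ends[i] <= n_pairs) f[ends[i]] <- max(f[ends[i]], toggle_floor[i])
  }
  used <- unique(c(starts, ends[ends <= n_pairs]))
  avail <- setdiff(10:90, used)
  s_blocks <- sort(sample(avail, length(detected)))
  f[s_blocks] <- pmax(f[s_blocks], 2)

  blob_ev <- if (n_blob > 0)
    data.frame(start_s = starts * interval, end_s = ends * interval,
               area_percent = areas, center_frac = fracs,
               angle_deg = NA_real_)
  else empty_blobs()
  stone_ev <- data.frame(target_id = detected, time_s = s_blocks * interval)

  scene_spec(motion_profile = f, blob_events = blob_ev,
             stone_events = stone_ev, session_time_min = t_min,
             group = kind,
             session_id = sprintf("%s_%02d", kind, trial),
             trial_index = trial, seed = seed_i)
}

#' Write a synthetic session to disk
#'
#' Emits a PNG frame directory (`frames/`), `annotation.json`,
#' `ground_truth.json` and the scene description (`scene_spec.json`).
#'
#' @param session A `synthetic_session` from [render_session()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synthetic_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frame_dir(session$stream, file.path(dir, "frames"))
  write_annotation(session$annotation, file.path(dir, "annotation.json"))
  jsonlite::write_json(session$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(session$spec), file.path(dir, "scene_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
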