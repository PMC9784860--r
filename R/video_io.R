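# Frame I/O: reading frame directories into timestamped grayscale frames and
# sampling frame pairs at a fixed time interval.

LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)  # ITU-R BT.601

#' Construct a single grayscale frame
#'
#' @param pixels Numeric matrix of grayscale intensities in \[0, 255\]
#'   (rows = y, columns = x).
#' @param index Non-negative frame index within its stream.
#' @param timestamp Seconds from session start.
#' @return A list of class `frame_sample` with fields `pixels`, `index`,
#'   `timestamp`, `width`, `height`.
#' @export
frame_sample <- function(pixels, index = 0L, timestamp = 0) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    abort_schema("`pixels` must be a non-empty numeric matrix")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    abort_schema("frame intensities must be finite and within [0, 255]")
  if (index < 0) abort_schema("`index` must be non-negative")
  structure(list(pixels = pixels, index = as.integer(index),
                 timestamp = as.numeric(timestamp),
                 width = ncol(pixels), height = nrow(pixels)),
            class = "frame_sample")
}

#' Convert an image array to grayscale
#'
#' RGB (or RGBA) arrays are reduced with the ITU-R BT.601 luma weights
#' 0.299 R + 0.587 G + 0.114 B, the convention of consumer capture hardware;
#' an alpha channel is ignored. Grayscale input is returned unchanged, so the
#' conversion is idempotent.
#'
#' @param x A numeric matrix (already gray) or a height x width x channels
#'   array, values in \[0, 255\].
#' @return A numeric matrix in \[0, 255\].
#' @export
to_gray <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    if (nc == 1L) return(x[, , 1L])
    if (nc %in% c(3L, 4L))
      return(LUMA_WEIGHTS[1] * x[, , 1L] + LUMA_WEIGHTS[2] * x[, , 2L] +
             LUMA_WEIGHTS[3] * x[, , 3L])
  }
  abort_schema("expected a matrix or an array with 1, 3 or 4 channels")
}

new_frame_stream <- function(frames, fps, source = "<memory>") {
  n <- length(frames)
  if (n == 0L) abort_io(sprintf("empty stream: %s", source))
  dims <- vapply(frames, function(f) c(f$height, f$width), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort_schema("all frames in a stream must share dimensions")
  structure(list(frames = frames,
                 meta = list(fps = fps, frame_count = n, duration = n / fps,
                             source = source)),
            class = "frame_stream")
}

#' Open a video source as a stream of grayscale frames
#'
#' Supported sources are directories of sequentially numbered image frames
#' (PNG or TIFF, 8-bit, lexicographically sortable zero-padded names), read
#' in sorted order and converted to grayscale. Container files (MP4/AVI/...)
#' must be extracted to a frame directory first (e.g. with
#' `ffmpeg -i in.mp4 frames/%06d.png`); no video decoder is bundled.
#'
#' Frames are never resized: all downstream percentages are relative to the
#' native frame size, which makes the metrics resolution-independent.
#'
#' @param source Path to a frame directory (or, unsupported, a container).
#' @param kind `"auto"` (directory => `"frame_dir"`), `"frame_dir"` or
#'   `"container"`.
#' @param fps Nominal capture rate used to timestamp frames (frames/second).
#'   Default 60, the capture rate of typical HDMI recorders.
#' @return A `frame_stream`: list with `frames` (list of [frame_sample()])
#'   and `meta` (`fps`, `frame_count`, `duration`, `source`).
#' @export
open_stream <- function(source, kind = c("auto", "frame_dir", "container"),
                        fps = 60) {
  kind <- match.arg(kind)
  if (kind == "auto")
    kind <- if (dir.exists(source)) "frame_dir" else "container"
  if (kind == "container")
    abort_io(paste0("video container decoding is not supported; extract the ",
                    "frames to a directory of PNG images (e.g. with ffmpeg) ",
                    "and open it with kind = 'frame_dir': ", source))
  if (!dir.exists(source)) abort_io(sprintf("frame directory not found: %s", source))
  files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    abort_io(sprintf("no PNG/TIFF frames found in %s", source))
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    ext <- tolower(tools::file_ext(files[i]))
    raw <- if (ext == "png") png::readPNG(files[i]) else tiff::readTIFF(files[i])
    px <- to_gray(raw * 255)
    frames[[i]] <- frame_sample(px, index = i - 1L, timestamp = (i - 1) / fps)
  }
  new_frame_stream(frames, fps = fps, source = source)
}

#' Build an in-memory stream from a list of pixel matrices
#'
#' @param mats List of numeric matrices (or 3-channel arrays) in \[0, 255\].
#' @param fps Frames per second used for timestamps.
#' @return A `frame_stream`.
#' @export
frame_stream <- function(mats, fps = 60) {
  frames <- lapply(seq_along(mats), function(i)
    frame_sample(to_gray(mats[[i]]), index = i - 1L, timestamp = (i - 1) / fps))
  new_frame_stream(frames, fps = fps)
}

#' Stream metadata
#'
#' @param stream A `frame_stream`.
#' @return List with `fps`, `frame_count`, `duration` (seconds) and `source`.
#' @export
stream_meta <- function(stream) {
  stopifnot(inherits(stream, "frame_stream"))
  stream$meta
}

#' Write a stream (or list of matrices) to a frame directory
#'
#' Frames are written as 8-bit grayscale PNGs with zero-padded names
#' (`frame_000001.png`, ...), the dialect [open_stream()] reads back.
#' Integer-valued input round-trips exactly.
#'
#' @param stream A `frame_stream` or list of numeric matrices in \[0, 255\].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frame_dir <- function(stream, dir) {
  mats <- if (inherits(stream, "frame_stream"))
    lapply(stream$frames, `[[`, "pixels") else stream
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(mats)) {
    png::writePNG(mats[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}

#' Sample frame pairs separated by a fixed time interval
#'
#' For each sampling time t = k * interval (k >= 1) up to the last frame's
#' timestamp, pairs the frame nearest t with the frame nearest t - interval
#' (nearest-frame rounding, so the timestamp error is bounded by half a
#' native frame period). A trailing partial interval is dropped; a stream
#' shorter than one interval yields an empty list.
#'
#' @param stream A `frame_stream`.
#' @param interval Pair separation in seconds. Default 0.3.
#' @return List of `frame_pair` objects: `current`, `previous`, `interval`.
#' @export
sample_pairs <- function(stream, interval = 0.3) {
  stopifnot(inherits(stream, "frame_stream"))
  if (!is_scalar_num(interval) || interval <= 0)
    abort_schema("`interval` must be a positive number of seconds")
  fps <- stream$meta$fps
  n <- stream$meta$frame_count
  last_ts <- stream$frames[[n]]$timestamp
  k_max <- floor(last_ts / interval + 1e-9)
  if (k_max < 1) return(list())
  lapply(seq_len(k_max), function(k) {
    i_cur <- min(n, max(1L, round(k * interval * fps) + 1L))
    i_prev <- min(n, max(1L, round((k - 1) * interval * fps) + 1L))
    structure(list(current = stream$frames[[i_cur]],
                   previous = stream$frames[[i_prev]],
                   interval = interval),
              class = "frame_pair")
  })
}

#' @export
print.frame_stream <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<frame_stream> %d frames, %.3g fps, %.2f s, %dx%d px (%s)\n",
              m$frame_count, m$fps, m$duration,
              x$frames[[1]]$width, x$frames[[1]]$height, m$source))
  invisible(x)
}
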