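# Fine Movement: frame differencing -> binarization -> coverage -> band score.
#
# The metric is a proxy for scope-tip speed: the absolute grayscale
# difference between two frames 0.3 s apart is thresholded, and the percent
# of changed pixels (coverage A_i) is scored 100 when it falls inside a
# calibrated band and 0 when the scope is too slow or too fast. The session
# score is the arithmetic mean over all sampled pairs.

#' Absolute difference image of a frame pair
#'
#' @param pair A `frame_pair` from [sample_pairs()], or a `frame_sample`
#'   (then `previous` must be supplied).
#' @param previous Optional second `frame_sample` when `pair` is a frame.
#' @return Numeric matrix of absolute grayscale differences in \[0, 255\].
#' @export
difference_image <- function(pair, previous = NULL) {
  if (inherits(pair, "frame_pair")) {
    a <- pair$current; b <- pair$previous
  } else {
    a <- pair; b <- previous
  }
  stopifnot(inherits(a, "frame_sample"), inherits(b, "frame_sample"))
  if (a$width != b$width || a$height != b$height)
    abort_schema("frames of a pair must share dimensions")
  abs(a$pixels - b$pixels)
}

#' Binarize a difference image at the motion threshold
#'
#' A pixel is marked changed when its difference strictly exceeds the
#' threshold.
#'
#' @param diff Numeric matrix of absolute differences.
#' @param threshold Grayscale threshold in (0, 255). Default 50.
#' @return 0/1 integer matrix of the same shape.
#' @export
binarize <- function(diff, threshold = 50) {
  if (!is.matrix(diff)) abort_schema("`diff` must be a matrix")
  if (!is_scalar_num(threshold) || threshold <= 0 || threshold >= 255)
    abort_schema("`threshold` must be in (0, 255)")
  mask <- diff > threshold
  storage.mode(mask) <- "integer"
  mask
}

#' Coverage percentage of a binary mask
#'
#' @param mask 0/1 matrix.
#' @return Percent of pixels set, in \[0, 100\].
#' @export
coverage <- function(mask) {
  if (!is.matrix(mask) || length(mask) == 0L)
    abort_schema("`mask` must be a non-empty matrix")
  100 * sum(mask != 0) / length(mask)
}

#' Per-pair Fine Movement score
#'
#' 100 when the coverage lies inside the (inclusive) band
#' `[eps_low, eps_high]`, else 0: only an appropriate moving speed scores,
#' too slow or too fast scores zero.
#'
#' @param coverage Coverage percentage(s) in \[0, 100\]; vectorized.
#' @param cfg A [motion_config()].
#' @return Numeric vector of 0/100 scores.
#' @export
frame_score <- function(coverage, cfg = motion_config()) {
  stopifnot(inherits(cfg, "motion_config"))
  if (any(!is.finite(coverage)) || any(coverage < 0) || any(coverage > 100))
    abort_schema("`coverage` must be within [0, 100]")
  ifelse(coverage >= cfg$eps_low & coverage <= cfg$eps_high, 100, 0)
}

#' Fine Movement score of a session
#'
#' Samples frame pairs at `cfg$interval`, computes each pair's coverage and
#' band score, and averages the scores over all pairs (zero-score pairs
#' included).
#'
#' @param stream A `frame_stream`.
#' @param cfg A [motion_config()].
#' @return A `motion_trace`: list with `samples` (data.frame of `timestamp`,
#'   `coverage`, `score`) and `session_score` in \[0, 100\].
#' @export
fine_movement <- function(stream, cfg = motion_config()) {
  stopifnot(inherits(cfg, "motion_config"))
  pairs <- sample_pairs(stream, cfg$interval)
  if (length(pairs) == 0L)
    abort_compute("stream is shorter than one sampling interval: Fine Movement undefined")
  cov <- vapply(pairs, function(p)
    coverage(binarize(difference_image(p), cfg$diff_threshold)), numeric(1))
  ts <- vapply(pairs, function(p) p$current$timestamp, numeric(1))
  sc <- frame_score(cov, cfg)
  structure(list(samples = data.frame(timestamp = ts, coverage = cov, score = sc),
                 session_score = mean(sc), config = cfg),
            class = "motion_trace")
}

#' Write a motion or exposure trace to CSV or JSON
#'
#' @param trace A `motion_trace` or `exposure_trace`.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, c("motion_trace", "exposure_trace")))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(trace$samples, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(samples = trace$samples,
                              session_score = trace$session_score),
                         path, digits = NA, auto_unbox = TRUE)
  } else abort_schema("trace format must be .csv or .json")
  invisible(path)
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d pairs, Fine Movement = %.1f\n",
              nrow(x$samples), x$session_score))
  invisible(x)
}
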