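# Target Detection and Efficiency, computed from the session annotation log.
#
# Detected targets come from the annotation, not from automated stone
# recognition: during a phantom session the operator (or a rater reviewing
# the recording) logs each renal calculus as it is exposed.

#' Construct a session annotation
#'
#' @param session_id Character identifier of the session.
#' @param group `"professional"` or `"trainee"`.
#' @param session_time_min Task completion time T, minutes (> 0).
#' @param detected data.frame with columns `target_id` and `time_s`
#'   (timestamp of each detection, seconds from session start); zero rows
#'   allowed.
#' @param total_targets Number of calculi placed in the phantom. Default 3.
#' @param trial_index Repetition number for the subject/group. Default 1.
#' @return A list of class `session_annotation`.
#' @export
session_annotation <- function(session_id, group = c("professional", "trainee"),
                               session_time_min,
                               detected = data.frame(target_id = character(0),
                                                     time_s = numeric(0)),
                               total_targets = 3, trial_index = 1) {
  group <- match.arg(group)
  if (!is.character(session_id) || length(session_id) != 1L || !nzchar(session_id))
    abort_schema("`session_id` must be a non-empty string")
  if (!is_scalar_num(session_time_min) || session_time_min <= 0)
    abort_schema("`session_time_min` must be a positive number of minutes")
  if (!is_scalar_num(total_targets) || total_targets < 1 ||
      total_targets != round(total_targets))
    abort_schema("`total_targets` must be a positive integer")
  if (!is.data.frame(detected) ||
      !all(c("target_id", "time_s") %in% names(detected)))
    abort_schema("`detected` must be a data.frame with columns target_id, time_s")
  detected$target_id <- as.character(detected$target_id)
  if (anyDuplicated(detected$target_id))
    abort_schema("detected target_ids must be unique")
  if (nrow(detected) > total_targets)
    abort_schema("more detections than placed targets")
  if (nrow(detected) && (any(!is.finite(detected$time_s)) || any(detected$time_s < 0)))
    abort_schema("detection timestamps must be non-negative seconds")
  structure(list(session_id = session_id, group = group,
                 trial_index = as.integer(trial_index),
                 total_targets = as.integer(total_targets),
                 session_time_min = session_time_min,
                 detected = detected[order(detected$time_s), , drop = FALSE]),
            class = "session_annotation")
}

#' Read a session annotation from JSON
#'
#' Expected fields: `session_id`, `group`, `session_time_min`,
#' `total_targets`, `trial_index` and `detected` (array of objects with
#' `target_id` and `time_s`). Validation errors name the offending field.
#'
#' @param path JSON file path.
#' @return A [session_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("annotation file not found: %s", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort_schema(sprintf(
                    "cannot parse annotation %s: %s", path, conditionMessage(e))))
  need <- c("session_id", "group", "session_time_min")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort_schema(sprintf("annotation %s: missing field(s) %s",
                         path, paste(miss, collapse = ", ")))
  det <- raw$detected
  if (is.null(det) || (is.data.frame(det) && nrow(det) == 0L) || length(det) == 0L)
    det <- data.frame(target_id = character(0), time_s = numeric(0))
  if (!is.data.frame(det))
    abort_schema(sprintf("annotation %s: `detected` must be an array of {target_id, time_s}", path))
  session_annotation(session_id = raw$session_id, group = raw$group,
                     session_time_min = raw$session_time_min, detected = det,
                     total_targets = raw$total_targets %||% 3,
                     trial_index = raw$trial_index %||% 1)
}

#' Write a session annotation to JSON
#'
#' @param ann A [session_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "session_annotation"))
  jsonlite::write_json(unclass(ann), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Target Detection score
#'
#' Percentage of placed renal calculi that were detected:
#' `100 * detected / total`.
#'
#' @param ann A [session_annotation()].
#' @return Percent in \[0, 100\].
#' @export
target_detection <- function(ann) {
  stopifnot(inherits(ann, "session_annotation"))
  if (ann$total_targets < 1) abort_schema("total_targets must be >= 1")
  100 * nrow(ann$detected) / ann$total_targets
}

#' Duration score
#'
#' `100 * (t_max - T) / t_max`: full marks in the limit of instantaneous
#' completion, 0 at the time budget. Sessions exceeding `t_max` would score
#' negative; by default the score is clamped at 0 (the unclamped value is
#' retained in the session scorecard).
#'
#' @param t_min Session time(s) T in minutes; vectorized.
#' @param cfg An [efficiency_config()].
#' @return Duration score(s), percent.
#' @export
duration_score <- function(t_min, cfg = efficiency_config()) {
  stopifnot(inherits(cfg, "efficiency_config"))
  if (any(!is.finite(t_min)) || any(t_min <= 0))
    abort_schema("session times must be positive minutes")
  raw <- 100 * (cfg$t_max - t_min) / cfg$t_max
  if (cfg$clamp_negative) pmax(0, raw) else raw
}

#' Efficiency score
#'
#' The two-term average of the Target Detection score and the mean Duration
#' score. With clamping active both operands lie in \[0, 100\], so the
#' result does too.
#'
#' @param td Target Detection score, percent.
#' @param durations Duration score(s), percent (one per trial when several
#'   trials are pooled).
#' @return Efficiency, percent.
#' @export
efficiency <- function(td, durations) {
  if (!is_scalar_num(td) || td < 0 || td > 100)
    abort_schema("`td` must be a percentage in [0, 100]")
  if (length(durations) < 1 || any(!is.finite(durations)) ||
      any(durations < 0) || any(durations > 100))
    abort_schema("`durations` must be percentages in [0, 100]")
  mean(c(td, mean(durations)))
}
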