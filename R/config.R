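# Configuration objects and error conditions.
#
# Every numeric constant the scoring pipeline uses lives in one of these
# config builders; computation code never hard-codes them.

stop_endoskill <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "endoskill_error", "error", "condition")))
}

abort_io      <- function(msg) stop_endoskill(msg, "endoskill_io_error")
abort_schema  <- function(msg) stop_endoskill(msg, "endoskill_schema_error")
abort_compute <- function(msg) stop_endoskill(msg, "endoskill_compute_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Motion (Fine Movement) configuration
#'
#' Parameters of the frame-differencing speed metric: the grayscale
#' difference threshold used to binarize the inter-frame difference image,
#' the coverage band (in percent of frame area) that counts as an
#' "appropriate" scope speed, and the sampling interval between the two
#' frames of a pair.
#'
#' `eps_low`/`eps_high` are calibration parameters: the threshold of 50 gray
#' levels and the 0.3 s interval are fixed constants of the method, while the
#' coverage band must be calibrated to the capture setup. The defaults
#' (0.5% and 20%) are the calibration the synthetic "professional" profile
#' is built around.
#'
#' @param diff_threshold Grayscale difference threshold (strictly exceeded
#'   pixels count as changed). Default 50.
#' @param eps_low,eps_high Inclusive coverage band, in percent of frame area,
#'   scoring 100; outside the band a pair scores 0. Defaults 0.5 and 20.
#' @param interval Time between the two frames of a pair, seconds. Default 0.3.
#' @return A list of class `motion_config`.
#' @export
motion_config <- function(diff_threshold = 50, eps_low = 0.5, eps_high = 20,
                          interval = 0.3) {
  if (!is_scalar_num(diff_threshold) || diff_threshold <= 0 || diff_threshold >= 255)
    abort_schema("`diff_threshold` must be a single number in (0, 255)")
  if (!is_scalar_num(eps_low) || !is_scalar_num(eps_high) ||
      eps_low < 0 || eps_low >= eps_high || eps_high > 100)
    abort_schema("coverage cutoffs must satisfy 0 <= eps_low < eps_high <= 100")
  if (!is_scalar_num(interval) || interval <= 0)
    abort_schema("`interval` must be a positive number of seconds")
  structure(list(diff_threshold = diff_threshold, eps_low = eps_low,
                 eps_high = eps_high, interval = interval),
            class = "motion_config")
}

#' Exposure (Visualization) configuration
#'
#' Parameters of the over-exposure metric: the saturation threshold above
#' which a pixel counts as over-exposed, the denoise step (size of the
#' morphological opening kernel and the minimum blob area kept), the radial
#' weight bands, and the evaluation cadence.
#'
#' @param saturation_threshold Pixels strictly above this grayscale value are
#'   over-exposed. Default 245.
#' @param min_blob_area Blobs smaller than this percent of frame area are
#'   discarded after opening. Default 0.02.
#' @param opening_size Side of the square structuring element for the
#'   morphological opening (odd; 0 disables opening). Default 3.
#' @param weight_breaks Radii, as fractions of the half-diagonal, separating
#'   the three weight bands. Default `c(1/3, 2/3)`.
#' @param weights Weights of the central, middle and outer band.
#'   Default `c(1, 2/3, 1/3)`.
#' @param interval Sampling cadence in seconds when `full_rate = FALSE`.
#'   Default 0.3, aligning the exposure trace with the motion trace.
#' @param full_rate Evaluate every frame instead of sampling at `interval`.
#' @return A list of class `exposure_config`.
#' @export
exposure_config <- function(saturation_threshold = 245, min_blob_area = 0.02,
                            opening_size = 3, weight_breaks = c(1/3, 2/3),
                            weights = c(1, 2/3, 1/3), interval = 0.3,
                            full_rate = FALSE) {
  if (!is_scalar_num(saturation_threshold) ||
      saturation_threshold <= 0 || saturation_threshold >= 255)
    abort_schema("`saturation_threshold` must be in (0, 255)")
  if (!is_scalar_num(min_blob_area) || min_blob_area < 0)
    abort_schema("`min_blob_area` must be >= 0 (percent of frame)")
  if (!is_scalar_num(opening_size) || opening_size < 0 ||
      (opening_size > 0 && opening_size %% 2 != 1))
    abort_schema("`opening_size` must be 0 (disabled) or an odd integer")
  if (length(weight_breaks) != 2 || any(diff(weight_breaks) <= 0) ||
      weight_breaks[1] <= 0 || weight_breaks[2] >= 1)
    abort_schema("`weight_breaks` must be two increasing fractions in (0, 1)")
  if (length(weights) != 3) abort_schema("`weights` must have three entries")
  if (!is_scalar_num(interval) || interval <= 0)
    abort_schema("`interval` must be a positive number of seconds")
  structure(list(saturation_threshold = saturation_threshold,
                 min_blob_area = min_blob_area, opening_size = opening_size,
                 weight_breaks = weight_breaks, weights = weights,
                 interval = interval, full_rate = isTRUE(full_rate)),
            class = "exposure_config")
}

#' Efficiency configuration
#'
#' @param t_max Maximum time allowed for the procedure, minutes. Default 5.
#' @param clamp_negative Clamp Duration scores below 0 (sessions longer than
#'   `t_max`) to 0 so all metrics stay on the 0-100 scale. Default TRUE.
#' @return A list of class `efficiency_config`.
#' @export
efficiency_config <- function(t_max = 5, clamp_negative = TRUE) {
  if (!is_scalar_num(t_max) || t_max <= 0)
    abort_schema("`t_max` must be a positive number of minutes")
  structure(list(t_max = t_max, clamp_negative = isTRUE(clamp_negative)),
            class = "efficiency_config")
}

#' Statistics configuration for group comparison
#'
#' @param alpha Significance level of the normality screen. Default 0.05.
#' @param p_threshold Two-sample test p-value below which a group difference
#'   is flagged significant. Default 0.01.
#' @param test Two-sample test: Welch t (default), pooled-variance t, or
#'   Wilcoxon rank-sum.
#' @param normality Normality screen: one-sample Kolmogorov-Smirnov against a
#'   normal with sample-estimated parameters (default; approximate), or the
#'   Lilliefors-corrected variant (requires the nortest package).
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, p_threshold = 0.01,
                         test = c("welch", "pooled", "wilcoxon"),
                         normality = c("ks", "lilliefors")) {
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1)
    abort_schema("`alpha` must be in (0, 1)")
  if (!is_scalar_num(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    abort_schema("`p_threshold` must be in (0, 1)")
  structure(list(alpha = alpha, p_threshold = p_threshold,
                 test = match.arg(test), normality = match.arg(normality)),
            class = "stats_config")
}

#' Full run configuration
#'
#' Bundles the per-metric configurations. All defaults equal the method's
#' stated constants (difference threshold 50, saturation threshold 245,
#' 0.3 s interval, Tmax = 5 min, alpha = 0.05, significance at p < 0.01).
#'
#' @param motion A [motion_config()].
#' @param exposure An [exposure_config()].
#' @param efficiency An [efficiency_config()].
#' @param stats A [stats_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(motion = motion_config(), exposure = exposure_config(),
                       efficiency = efficiency_config(), stats = stats_config()) {
  stopifnot(inherits(motion, "motion_config"),
            inherits(exposure, "exposure_config"),
            inherits(efficiency, "efficiency_config"),
            inherits(stats, "stats_config"))
  structure(list(motion = motion, exposure = exposure,
                 efficiency = efficiency, stats = stats),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may contain any subset of the sections `motion`, `exposure`,
#' `efficiency` and `stats`; each section any subset of the corresponding
#' builder's arguments. Omitted values keep their defaults. Unknown sections
#' or fields are schema errors.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_schema(sprintf(
                    "cannot parse config %s: %s", path, conditionMessage(e))))
  raw <- raw %||% list()
  known <- c("motion", "exposure", "efficiency", "stats")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    abort_schema(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")))
  build <- function(builder, section) {
    args <- raw[[section]] %||% list()
    extra <- setdiff(names(args), names(formals(builder)))
    if (length(extra))
      abort_schema(sprintf("unknown field(s) in config section '%s': %s",
                           section, paste(extra, collapse = ", ")))
    do.call(builder, args)
  }
  run_config(motion = build(motion_config, "motion"),
             exposure = build(exposure_config, "exposure"),
             efficiency = build(efficiency_config, "efficiency"),
             stats = build(stats_config, "stats"))
}

#' Write the resolved run configuration next to run outputs
#'
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- lapply(config, function(x) lapply(unclass(x), identity))
  yaml::write_yaml(lst, path)
  invisible(path)
}
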