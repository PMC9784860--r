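# Session scorecards, group statistics and figures.

#' Score one session: all four metrics
#'
#' Runs Fine Movement and Visualization on the video stream and Target
#' Detection and Efficiency on the annotation log. Deterministic given
#' inputs and config; no partial scorecard is ever returned (any upstream
#' error propagates).
#'
#' @param stream A `frame_stream` (or a frame-directory path, opened with
#'   the stream's native fps taken from `fps`).
#' @param annotation A [session_annotation()] (or a JSON path).
#' @param config A [run_config()].
#' @param fps Frames/second used when `stream` is a path. Default 60.
#' @return A `session_scorecard`: scores, timing and the two traces.
#' @export
score_session <- function(stream, annotation, config = run_config(), fps = 60) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(stream)) stream <- open_stream(stream, fps = fps)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  stopifnot(inherits(stream, "frame_stream"),
            inherits(annotation, "session_annotation"))
  motion <- fine_movement(stream, config$motion)
  expo <- visualization(stream, config$exposure)
  td <- target_detection(annotation)
  dur_raw <- 100 * (config$efficiency$t_max - annotation$session_time_min) /
    config$efficiency$t_max
  dur <- duration_score(annotation$session_time_min, config$efficiency)
  eff <- efficiency(td, dur)
  structure(list(session_id = annotation$session_id,
                 group = annotation$group,
                 trial_index = annotation$trial_index,
                 target_detection = td,
                 fine_movement = motion$session_score,
                 visualization = expo$session_score,
                 efficiency = eff,
                 efficiency_sum = td + dur,
                 duration = dur,
                 duration_unclamped = dur_raw,
                 session_time_min = annotation$session_time_min,
                 traces = list(motion = motion, exposure = expo),
                 config = config),
            class = "session_scorecard")
}

#' @export
print.session_scorecard <- function(x, ...) {
  cat(sprintf("<session_scorecard> %s (%s, trial %d)\n", x$session_id,
              x$group, x$trial_index))
  cat(sprintf("  Target Detection %.1f | Fine Movement %.1f | Visualization %.1f | Efficiency %.1f\n",
              x$target_detection, x$fine_movement, x$visualization, x$efficiency))
  cat(sprintf("  T = %.2f min (Duration %.1f, unclamped %.1f)\n",
              x$session_time_min, x$duration, x$duration_unclamped))
  invisible(x)
}

#' Tabulate scorecards
#'
#' @param scorecards A single `session_scorecard` or a list of them.
#' @return data.frame with one row per session.
#' @export
scorecard_table <- function(scorecards) {
  if (inherits(scorecards, "session_scorecard")) scorecards <- list(scorecards)
  rows <- lapply(scorecards, function(s) {
    stopifnot(inherits(s, "session_scorecard"))
    data.frame(session_id = s$session_id, group = s$group,
               trial_index = s$trial_index,
               target_detection = s$target_detection,
               fine_movement = s$fine_movement,
               visualization = s$visualization,
               efficiency = s$efficiency,
               efficiency_sum = s$efficiency_sum,
               duration = s$duration,
               duration_unclamped = s$duration_unclamped,
               session_time_min = s$session_time_min)
  })
  do.call(rbind, rows)
}

#' Write a scorecard (table + traces) to a directory
#'
#' Emits `scorecard.csv`, `scorecard.json`, `motion_trace.csv` and
#' `exposure_trace.csv`.
#'
#' @param scorecard A `session_scorecard`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scorecard <- function(scorecard, dir) {
  stopifnot(inherits(scorecard, "session_scorecard"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- scorecard_table(scorecard)
  utils::write.csv(tab, file.path(dir, "scorecard.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(tab), file.path(dir, "scorecard.json"),
                       auto_unbox = FALSE, digits = NA)
  write_trace(scorecard$traces$motion, file.path(dir, "motion_trace.csv"))
  write_trace(scorecard$traces$exposure, file.path(dir, "exposure_trace.csv"))
  invisible(dir)
}

#' Read scorecard tables back into one data.frame
#'
#' @param paths CSV files written by [write_scorecard()] (or directories
#'   containing a `scorecard.csv`).
#' @return Combined data.frame.
#' @export
read_scorecards <- function(paths) {
  files <- vapply(paths, function(p) {
    if (dir.exists(p)) p <- file.path(p, "scorecard.csv")
    if (!file.exists(p)) abort_io(sprintf("scorecard not found: %s", p))
    p
  }, character(1))
  do.call(rbind, lapply(files, utils::read.csv))
}

normality_p <- function(x, method) {
  if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
  if (method == "lilliefors") {
    if (!requireNamespace("nortest", quietly = TRUE))
      abort_schema("normality = 'lilliefors' requires the nortest package")
    return(suppressWarnings(nortest::lillie.test(x)$p.value))
  }
  # One-sample KS against a normal with sample-estimated parameters;
  # approximate (estimation makes the nominal p conservative).
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
}

#' Compare one metric between groups
#'
#' Screens each group for normality, then applies an unpaired two-tailed
#' two-sample test (Welch t by default) and flags significance at
#' `p_threshold`.
#'
#' @param scores data.frame with a `group` column and the metric column
#'   (e.g. from [scorecard_table()]), or a list of scorecards.
#' @param metric Column name to compare (e.g. `"fine_movement"`).
#' @param cfg A [stats_config()].
#' @return A `group_comparison`: metric name, per-group n/mean/sd/normality
#'   p, test name, `t` (statistic), `df`, `p_value`, `significant`.
#' @export
compare_groups <- function(scores, metric, cfg = stats_config()) {
  stopifnot(inherits(cfg, "stats_config"))
  if (!is.data.frame(scores)) scores <- scorecard_table(scores)
  if (!metric %in% names(scores))
    abort_schema(sprintf("metric '%s' not found in scores", metric))
  if (!"group" %in% names(scores)) abort_schema("scores need a `group` column")
  groups <- split(scores[[metric]], scores$group)
  if (length(groups) != 2L)
    abort_schema(sprintf("need exactly 2 groups, got %d", length(groups)))
  if (any(vapply(groups, length, integer(1)) < 2L))
    abort_compute("each group needs at least 2 sessions")
  g1 <- groups[[1]]; g2 <- groups[[2]]
  ht <- switch(cfg$test,
    welch   = stats::t.test(g1, g2, var.equal = FALSE),
    pooled  = stats::t.test(g1, g2, var.equal = TRUE),
    wilcoxon = suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE)))
  structure(list(metric = metric,
                 groups = data.frame(group = names(groups),
                                     n = c(length(g1), length(g2)),
                                     mean = c(mean(g1), mean(g2)),
                                     sd = c(stats::sd(g1), stats::sd(g2)),
                                     normality_p = c(normality_p(g1, cfg$normality),
                                                     normality_p(g2, cfg$normality))),
                 test = cfg$test,
                 t = unname(ht$statistic),
                 df = unname(ht$parameter %||% NA_real_),
                 p_value = ht$p.value,
                 alpha = cfg$alpha,
                 p_threshold = cfg$p_threshold,
                 significant = ht$p.value < cfg$p_threshold),
            class = "group_comparison")
}

#' Compare all four metrics between groups
#'
#' @param scores data.frame or list of scorecards, two groups.
#' @param metrics Metric columns to compare.
#' @param cfg A [stats_config()].
#' @return data.frame, one row per metric, with group means/sds, the test
#'   statistic, p-value and significance flag.
#' @export
compare_all_metrics <- function(scores,
                                metrics = c("target_detection", "fine_movement",
                                            "visualization", "efficiency"),
                                cfg = stats_config()) {
  rows <- lapply(metrics, function(m) {
    cmp <- compare_groups(scores, m, cfg)
    g <- cmp$groups
    data.frame(metric = m,
               group1 = g$group[1], n1 = g$n[1], mean1 = g$mean[1], sd1 = g$sd[1],
               normality_p1 = g$normality_p[1],
               group2 = g$group[2], n2 = g$n[2], mean2 = g$mean[2], sd2 = g$sd[2],
               normality_p2 = g$normality_p[2],
               test = cmp$test, t = cmp$t, df = cmp$df,
               p_value = cmp$p_value, significant = cmp$significant)
  })
  do.call(rbind, rows)
}

#' @export
print.group_comparison <- function(x, ...) {
  g <- x$groups
  cat(sprintf("<group_comparison> %s (%s test)\n", x$metric, x$test))
  for (i in 1:2)
    cat(sprintf("  %-12s n=%d mean=%.2f sd=%.2f (normality p=%.3g)\n",
                g$group[i], g$n[i], g$mean[i], g$sd[i], g$normality_p[i]))
  cat(sprintf("  t = %.3f, p = %.4g -> %ssignificant at p < %g\n",
              x$t, x$p_value, if (x$significant) "" else "not ", x$p_threshold))
  invisible(x)
}

#' Histogram of per-pair coverage with a normal fit
#'
#' Pools the coverage values (A_i) of one or more motion traces, bins them
#' and fits a normal distribution by maximum likelihood (mean, and SD with
#' the 1/n denominator). An all-equal sample gives SD 0 and is flagged
#' degenerate.
#'
#' @param traces A `motion_trace`, a list of them, or a numeric vector of
#'   coverages.
#' @param bins Number of histogram bins. Default 30.
#' @return A `movement_histogram`: `breaks`, `counts`, `mids`, `n`, `mean`,
#'   `sd`, `degenerate`.
#' @export
movement_histogram <- function(traces, bins = 30) {
  x <- if (is.numeric(traces)) traces
  else {
    if (inherits(traces, "motion_trace")) traces <- list(traces)
    unlist(lapply(traces, function(t) {
      stopifnot(inherits(t, "motion_trace")); t$samples$coverage
    }))
  }
  if (length(x) == 0L) abort_compute("no coverage samples to histogram")
  mu <- mean(x)
  sd_ml <- sqrt(mean((x - mu)^2))
  degenerate <- sd_ml == 0
  breaks <- if (degenerate) c(x[1] - 0.5, x[1] + 0.5)
  else seq(min(x), max(x), length.out = bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 n = length(x), mean = mu, sd = sd_ml, degenerate = degenerate),
            class = "movement_histogram")
}

#' Plot a movement histogram with its normal fit
#'
#' @param h A [movement_histogram()].
#' @return A ggplot object.
#' @export
plot_movement_histogram <- function(h) {
  stopifnot(inherits(h, "movement_histogram"))
  df <- data.frame(mid = h$mids, count = h$counts)
  width <- diff(h$breaks)[1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = width, fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = "coverage per pair (%)", y = "count") +
    ggplot2::theme_minimal()
  if (!h$degenerate) {
    xs <- seq(h$breaks[1], h$breaks[length(h$breaks)], length.out = 200)
    fit <- data.frame(x = xs,
                      y = stats::dnorm(xs, h$mean, h$sd) * h$n * width)
    p <- p + ggplot2::geom_line(data = fit,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                color = "firebrick")
  }
  p
}

#' Group score bars with SD error bars
#'
#' @param scores Scorecard data.frame (two groups).
#' @param metrics Metric columns to display.
#' @return A ggplot object.
#' @export
plot_group_scores <- function(scores,
                              metrics = c("target_detection", "fine_movement",
                                          "visualization", "efficiency")) {
  if (!is.data.frame(scores)) scores <- scorecard_table(scores)
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(group = scores$group, metric = m, value = scores[[m]])))
  agg <- stats::aggregate(value ~ group + metric, long,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  agg <- cbind(agg[c("group", "metric")], as.data.frame(agg$value))
  agg$metric <- factor(agg$metric, levels = metrics)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$metric, y = .data$mean,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "score (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 105)) +
    ggplot2::theme_minimal()
}

#' Per-session trace curve
#'
#' @param trace A `motion_trace` or `exposure_trace`.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  stopifnot(inherits(trace, c("motion_trace", "exposure_trace")))
  ycol <- if (inherits(trace, "motion_trace")) "coverage" else "weighted_area"
  df <- trace$samples
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp, y = .data[[ycol]])) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (s)",
                  y = if (ycol == "coverage") "coverage A (%)" else "weighted area wA (%)") +
    ggplot2::theme_minimal()
}
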