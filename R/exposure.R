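# Visualization: over-exposure masking, denoising, blob measurement and the
# centre-weighted area score.
#
# Saturated (over-exposed) regions carry no diagnostic information and often
# indicate the scope tip touching the wall. Each frame's saturated blobs are
# extracted after a denoise step; a blob's area percentage is weighted by how
# central its centroid is (central saturation is worst), and the frame takes
# the maximum weighted area over its blobs. The session score is
# 100 * (1 - mean weighted-area fraction).

#' Over-exposure mask of a frame
#'
#' @param frame A `frame_sample` (or plain matrix in \[0, 255\]).
#' @param cfg An [exposure_config()].
#' @return 0/1 integer matrix: 1 where intensity strictly exceeds the
#'   saturation threshold.
#' @export
overexposure_mask <- function(frame, cfg = exposure_config()) {
  stopifnot(inherits(cfg, "exposure_config"))
  px <- if (inherits(frame, "frame_sample")) frame$pixels else frame
  if (!is.matrix(px)) abort_schema("`frame` must be a frame_sample or matrix")
  mask <- px > cfg$saturation_threshold
  storage.mode(mask) <- "integer"
  mask
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels that
# touch diagonally with a union-find over the (small) label graph.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  edges <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # up-right
  edges <- edges[edges[, 1] > 0L & edges[, 2] > 0L & edges[, 1] != edges[, 2], ,
                 drop = FALSE]
  if (nrow(edges) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Denoise an over-exposure mask and measure its blobs
#'
#' Denoising is a morphological opening with a square kernel followed by an
#' area filter; surviving 8-connected components are measured. The centroid
#' is the unweighted mean of member pixel coordinates; the distance is from
#' the frame centre to the centroid, compared against the half-diagonal.
#'
#' @param mask 0/1 matrix from [overexposure_mask()].
#' @param cfg An [exposure_config()].
#' @return data.frame with one row per blob: `x`, `y` (centroid, pixels),
#'   `area_percent`, `distance` (pixels), `weight`, `weighted_area`.
#' @export
denoise_and_blobs <- function(mask, cfg = exposure_config()) {
  stopifnot(inherits(cfg, "exposure_config"))
  if (!is.matrix(mask) || length(mask) == 0L)
    abort_schema("`mask` must be a non-empty matrix")
  nr <- nrow(mask); nc <- ncol(mask)
  m <- mask != 0
  storage.mode(m) <- "integer"
  if (cfg$opening_size > 0 && any(m > 0)) {
    kern <- EBImage::makeBrush(cfg$opening_size, shape = "box")
    m <- EBImage::opening(m, kern)
    m <- matrix(as.integer(m > 0), nr, nc)
  }
  empty <- data.frame(x = numeric(0), y = numeric(0), area_percent = numeric(0),
                      distance = numeric(0), weight = numeric(0),
                      weighted_area = numeric(0))
  if (!any(m > 0)) return(empty)
  lab <- label_components_8(m)
  ids <- which(lab > 0L)
  labs <- lab[ids]
  area <- tabulate(labs)
  rows <- ((ids - 1L) %% nr) + 1L
  cols <- ((ids - 1L) %/% nr) + 1L
  cy <- rowsum(as.numeric(rows), labs)[, 1] / area
  cx <- rowsum(as.numeric(cols), labs)[, 1] / area
  area_percent <- 100 * area / (nr * nc)
  keep <- area_percent >= cfg$min_blob_area
  if (!any(keep)) return(empty)
  cx <- cx[keep]; cy <- cy[keep]; area_percent <- area_percent[keep]
  ox <- (nc + 1) / 2; oy <- (nr + 1) / 2
  r <- sqrt(nc^2 + nr^2) / 2
  d <- sqrt((cx - ox)^2 + (cy - oy)^2)
  w <- weight_for_distance(d, r, cfg)
  data.frame(x = cx, y = cy, area_percent = area_percent, distance = d,
             weight = w, weighted_area = w * area_percent)
}

#' Radial weight of a blob centroid
#'
#' Central saturation is weighted most heavily: weight 1 for distances up to
#' a third of the half-diagonal r, 2/3 between r/3 and 2r/3 (exclusive), and
#' 1/3 from 2r/3 out to r.
#'
#' @param d Centroid-to-frame-centre distance(s), pixels; must satisfy
#'   0 <= d <= r.
#' @param r Half-diagonal of the frame, pixels.
#' @param cfg An [exposure_config()] supplying the band breaks and weights.
#' @return Numeric vector of weights.
#' @export
weight_for_distance <- function(d, r, cfg = exposure_config()) {
  stopifnot(inherits(cfg, "exposure_config"))
  if (!is_scalar_num(r) || r <= 0) abort_schema("`r` must be a positive scalar")
  if (any(!is.finite(d)) || any(d < 0) || any(d > r * (1 + 1e-9)))
    abort_schema("distances must satisfy 0 <= d <= r")
  b <- cfg$weight_breaks * r
  ifelse(d <= b[1], cfg$weights[1],
         ifelse(d < b[2], cfg$weights[2], cfg$weights[3]))
}

#' Weighted over-exposed area of one frame
#'
#' Each surviving blob contributes weight x area percent; the frame's value
#' is the maximum over blobs (0 when no blob survives denoising), capped
#' at 100.
#'
#' @param frame A `frame_sample` or matrix.
#' @param cfg An [exposure_config()].
#' @return Weighted area percent wA in \[0, 100\].
#' @export
frame_exposure <- function(frame, cfg = exposure_config()) {
  blobs <- denoise_and_blobs(overexposure_mask(frame, cfg), cfg)
  if (nrow(blobs) == 0L) return(0)
  min(100, max(blobs$weighted_area))
}

#' Visualization score of a session
#'
#' Evaluates the weighted over-exposed area wA on frames sampled at the
#' configured cadence (default 0.3 s, aligning with the motion trace;
#' `full_rate = TRUE` evaluates every frame) and scores
#' `100 * (1 - mean(wA) / 100)`, clamped to \[0, 100\]. A blob-free video
#' scores 100.
#'
#' @param stream A `frame_stream`.
#' @param cfg An [exposure_config()].
#' @return An `exposure_trace`: list with `samples` (data.frame of
#'   `timestamp`, `weighted_area`) and `session_score`.
#' @export
visualization <- function(stream, cfg = exposure_config()) {
  stopifnot(inherits(stream, "frame_stream"), inherits(cfg, "exposure_config"))
  n <- stream$meta$frame_count
  if (n == 0L) abort_compute("empty stream: Visualization undefined")
  if (cfg$full_rate) {
    idx <- seq_len(n)
  } else {
    fps <- stream$meta$fps
    last_ts <- stream$frames[[n]]$timestamp
    ks <- 0:floor(last_ts / cfg$interval + 1e-9)
    idx <- unique(pmin(n, pmax(1L, round(ks * cfg$interval * fps) + 1L)))
  }
  wa <- vapply(idx, function(i) frame_exposure(stream$frames[[i]], cfg), numeric(1))
  ts <- vapply(idx, function(i) stream$frames[[i]]$timestamp, numeric(1))
  score <- min(100, max(0, (1 - mean(wa) / 100) * 100))
  structure(list(samples = data.frame(timestamp = ts, weighted_area = wa),
                 session_score = score, config = cfg),
            class = "exposure_trace")
}

#' @export
print.exposure_trace <- function(x, ...) {
  cat(sprintf("<exposure_trace> %d frames, Visualization = %.1f\n",
              nrow(x$samples), x$session_score))
  invisible(x)
}
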