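# Independent brute-force oracles (deliberately unvectorized / naive) and
# small fixture builders shared by the tests.

# Nested-loop absolute difference of two matrices.
brute_diff <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(a))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      out[i, j] <- abs(a[i, j] - b[i, j])
  out
}

# Elementwise strict thresholding via loops.
brute_binarize <- function(d, th) {
  out <- matrix(0L, nrow(d), ncol(d))
  for (i in seq_len(nrow(d)))
    for (j in seq_len(ncol(d)))
      out[i, j] <- if (d[i, j] > th) 1L else 0L
  out
}

# Counting loop for coverage percent.
brute_coverage <- function(m) {
  cnt <- 0
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      if (m[i, j] != 0) cnt <- cnt + 1
  100 * cnt / (nrow(m) * ncol(m))
}

# 8-connected components by explicit flood fill (stack-based BFS).
flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (mask[i0, j0] != 0 && lab[i0, j0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i0, j0))
      lab[i0, j0] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          i <- p[1] + di; j <- p[2] + dj
          if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
              mask[i, j] != 0 && lab[i, j] == 0L) {
            lab[i, j] <- cur
            stack[[length(stack) + 1L]] <- c(i, j)
          }
        }
      }
    }
  }
  lab
}

# Blob measurements (area %, centroid, max weighted area) from a flood-fill
# labeling: the reference for frame_exposure with denoising disabled.
brute_max_weighted_area <- function(mask, weights = c(1, 2/3, 1/3)) {
  lab <- flood_components(mask)
  n <- max(lab)
  if (n == 0L) return(0)
  nr <- nrow(mask); nc <- ncol(mask)
  ox <- (nc + 1) / 2; oy <- (nr + 1) / 2
  r <- sqrt(nc^2 + nr^2) / 2
  best <- 0
  for (l in seq_len(n)) {
    idx <- which(lab == l, arr.ind = TRUE)
    area_pct <- 100 * nrow(idx) / (nr * nc)
    d <- sqrt((mean(idx[, 2]) - ox)^2 + (mean(idx[, 1]) - oy)^2)
    w <- if (d <= r / 3) weights[1] else if (d < 2 * r / 3) weights[2] else weights[3]
    best <- max(best, w * area_pct)
  }
  best
}

# A stream of integer-valued random frames.
random_stream <- function(n_frames, nr = 8, nc = 8, fps = 10, seed = 1) {
  set.seed(seed)
  mats <- replicate(n_frames, matrix(sample(0:255, nr * nc, TRUE), nr, nc),
                    simplify = FALSE)
  frame_stream(mats, fps = fps)
}

# A stream whose sampled pairs change an exact pixel fraction, built
# independently of the synthetic generator (block-constant frames).
fraction_stream <- function(fracs, nr = 20, nc = 20, fps = 10, fpb = 3,
                            delta = 80, seed = 1) {
  set.seed(seed)
  n_px <- nr * nc
  base <- matrix(sample(40:140, n_px, TRUE), nr, nc)
  keyframes <- list(base)
  for (f in fracs) {
    k <- round(f * n_px / 100)
    m <- keyframes[[length(keyframes)]]
    if (k > 0) {
      pick <- sample.int(n_px, k)
      m[pick] <- ifelse(m[pick] <= 127, m[pick] + delta, m[pick] - delta)
    }
    keyframes[[length(keyframes) + 1L]] <- m
  }
  mats <- unlist(lapply(keyframes, function(m) replicate(fpb, m, simplify = FALSE)),
                 recursive = FALSE)
  frame_stream(mats, fps = fps)
}

# Frame with solid saturated rectangles on a dark background.
frame_with_rects <- function(nr, nc, rects, value = 255, bg = 100) {
  m <- matrix(bg, nr, nc)
  for (rc in rects) m[rc$rows, rc$cols] <- value
  m
}
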