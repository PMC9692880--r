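# Independent oracles used to cross-check the analytic implementations.

# Rasterized IoU: cover the smallest region enclosing both boxes with an
# n x n grid of cell midpoints and count cells falling in each box.
# Boxes are axis-aligned, so the 2-D counts factor into per-axis counts.
raster_iou <- function(a, b, n = 1000L) {
  a <- as.numeric(a); b <- as.numeric(b)
  x0 <- min(a[1], b[1]); x1 <- max(a[3], b[3])
  y0 <- min(a[2], b[2]); y1 <- max(a[4], b[4])
  xs <- x0 + (seq_len(n) - 0.5) * (x1 - x0) / n
  ys <- y0 + (seq_len(n) - 0.5) * (y1 - y0) / n
  cnt <- function(lo, hi, v) sum(v >= lo & v <= hi)
  in_a <- cnt(a[1], a[3], xs) * cnt(a[2], a[4], ys)
  in_b <- cnt(b[1], b[3], xs) * cnt(b[2], b[4], ys)
  in_ab <- cnt(max(a[1], b[1]), min(a[3], b[3]), xs) *
           cnt(max(a[2], b[2]), min(a[4], b[4]), ys)
  in_ab / (in_a + in_b - in_ab)
}

# Brute-force greedy NMS over a precomputed similarity matrix: scan for
# the best-scoring live box, keep it, kill everything too similar.
nms_oracle <- function(b, scores, metric_fn, scale = NULL, threshold = 0.5) {
  n <- nrow(b)
  sim <- matrix(NA_real_, n, n)
  for (i in seq_len(n))
    sim[, i] <- metric_fn(b, b[i, , drop = FALSE], scale)
  alive <- rep(TRUE, n)
  kept <- integer(0)
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[which.max(scores[cand])]  # which.max: lowest index on ties
    kept <- c(kept, best)
    alive[best] <- FALSE
    alive[alive & sim[, best] >= threshold] <- FALSE
  }
  kept
}

# Random valid boxes with centers in [0, span]^2 and sides in side_range.
random_boxes <- function(n, span = 512, side_range = c(1, 64)) {
  cx <- runif(n, 0, span)
  cy <- runif(n, 0, span)
  w <- runif(n, side_range[1], side_range[2])
  h <- runif(n, side_range[1], side_range[2])
  boxes(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

# Integer-coordinate boxes (for rasterization cross-checks).
random_int_boxes <- function(n, span = 40, max_side = 16) {
  x0 <- sample.int(span, n, replace = TRUE)
  y0 <- sample.int(span, n, replace = TRUE)
  w <- sample(2:max_side, n, replace = TRUE)
  h <- sample(2:max_side, n, replace = TRUE)
  boxes(x0, y0, x0 + w, y0 + h)
}
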