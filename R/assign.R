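#' Generate an anchor grid over an image
#'
#' Tiles one anchor per (size, aspect ratio) at each feature-grid cell
#' center. Cell centers sit at `(i + 0.5) * stride` for
#' `i = 0 ... floor(dim/stride) - 1`. Each anchor has area `size^2` and
#' width/height ratio `ratio`, i.e. `w = size * sqrt(ratio)`,
#' `h = size / sqrt(ratio)`, so the three default ratios share one area.
#' Anchors are not clipped to the image by default, following standard
#' region-proposal practice; qualities are computed on the raw anchors.
#'
#' Defaults mirror the dense small-object setup: sizes
#' `(8, 16, 32, 64, 128)` and ratios `(0.5, 1, 2)`.
#'
#' Anchor order is deterministic: cells in row-major order (y outer,
#' x inner), then sizes, then ratios innermost.
#'
#' @param image_w,image_h image dimensions in pixels.
#' @param stride grid stride in pixels.
#' @param sizes numeric vector of anchor scales (pixels).
#' @param ratios numeric vector of width/height aspect ratios.
#' @param clip if `TRUE`, clip anchors to the image bounds (anchors whose
#'   clipped form would be degenerate are left unclipped).
#' @return an object of class `"anchor_grid"`: a list with `anchors`
#'   (a `boxes` matrix), `stride`, `sizes`, `ratios`, `grid_w`, `grid_h`.
#' @examples
#' g <- generate_anchors(16, 16, stride = 16, sizes = 8, ratios = 1)
#' g$anchors  # one 8x8 anchor centered at (8, 8)
#' @export
generate_anchors <- function(image_w, image_h, stride = 16,
                             sizes = c(8, 16, 32, 64, 128),
                             ratios = c(0.5, 1, 2),
                             clip = FALSE) {
  if (length(sizes) == 0L || length(ratios) == 0L)
    stop("sizes and ratios must be non-empty")
  if (image_w <= 0 || image_h <= 0 || stride <= 0)
    stop("image dimensions and stride must be positive")
  grid_w <- floor(image_w / stride)
  grid_h <- floor(image_h / stride)
  if (grid_w < 1L || grid_h < 1L)
    stop("stride larger than the image: no grid cells")

  cx1 <- (seq_len(grid_w) - 0.5) * stride
  cy1 <- (seq_len(grid_h) - 0.5) * stride
  w1 <- as.vector(outer(sizes, sqrt(ratios)))       # ratio innermost
  h1 <- as.vector(outer(sizes, 1 / sqrt(ratios)))
  k <- length(w1)

  cx <- rep(rep(cx1, each = k), times = grid_h)
  cy <- rep(cy1, each = k * grid_w)
  w <- rep_len(w1, length(cx))
  h <- rep_len(h1, length(cx))
  a <- boxes(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  if (clip) {
    cl <- cbind(pmax(a[, 1L], 0), pmax(a[, 2L], 0),
                pmin(a[, 3L], image_w), pmin(a[, 4L], image_h))
    ok <- cl[, 3L] > cl[, 1L] & cl[, 4L] > cl[, 2L]
    a[ok, ] <- cl[ok, ]
  }
  structure(list(anchors = a, stride = stride, sizes = sizes,
                 ratios = ratios, grid_w = grid_w, grid_h = grid_h),
            class = "anchor_grid")
}

#' @export
print.anchor_grid <- function(x, ...) {
  cat(sprintf("anchor grid: %d x %d cells, stride %g, %d sizes x %d ratios = %d anchors\n",
              x$grid_w, x$grid_h, x$stride, length(x$sizes), length(x$ratios),
              nrow(x$anchors)))
  invisible(x)
}

as_anchor_boxes <- function(anchors) {
  if (inherits(anchors, "anchor_grid")) anchors$anchors else as_boxes(anchors)
}

#' Assign training labels to anchors by box similarity
#'
#' Each anchor's quality is its best similarity to any ground truth
#' under the chosen metric. Anchors at or above `pos_threshold` are
#' positive, below `neg_threshold` negative, in between ignored. With
#' `force_match` (the classic low-quality rescue), every ground truth
#' additionally claims its best-quality anchor as positive regardless of
#' threshold — the rescue that keeps small objects, whose IoU with every
#' anchor can be tiny, from going unmatched.
#'
#' When two ground truths share the same best anchor, each ground truth
#' (in input order) claims its best not-yet-claimed anchor, ranked by
#' quality with ties broken by lowest anchor index; this keeps the
#' one-positive-per-gt guarantee whenever there are at least as many
#' anchors as ground truths.
#'
#' Default thresholds mirror the classic IoU convention
#' (positive 0.7 / negative 0.3). On the TSD scale these defaults share
#' IoU's "1 = perfect" calibration but are otherwise a convention, not a
#' validated choice; TSD qualities can be negative and are used raw,
#' with no flooring.
#'
#' @param anchors an [generate_anchors()] grid or a `boxes` matrix.
#' @param gts a `boxes` matrix of ground truths, or `NULL`/empty for a
#'   scene with no objects (all anchors negative, quality `-Inf`).
#' @param metric_name a registered metric name (see [list_metrics()]).
#' @inheritParams tsd
#' @param pos_threshold,neg_threshold quality thresholds with
#'   `pos_threshold >= neg_threshold`.
#' @param force_match logical; see above.
#' @return an object of class `"match_result"`: a data frame with
#'   per-anchor columns `label` (factor positive/negative/ignore),
#'   `matched_gt` (index into `gts`, `NA` if none) and `quality`.
#' @export
assign_labels <- function(anchors, gts, metric_name = "iou", scale = NULL,
                          pos_threshold = 0.7, neg_threshold = 0.3,
                          force_match = TRUE) {
  a <- as_anchor_boxes(anchors)
  metric <- box_metric(metric_name)
  if (pos_threshold < neg_threshold)
    stop("pos_threshold must be >= neg_threshold")
  n <- nrow(a)

  if (is.null(gts) || (is.matrix(gts) && nrow(gts) == 0L)) {
    out <- data.frame(
      label = factor(rep("negative", n), levels = label_levels()),
      matched_gt = rep(NA_integer_, n),
      quality = rep(-Inf, n))
    class(out) <- c("match_result", class(out))
    return(out)
  }
  g <- as_boxes(gts)
  q <- quality_matrix(a, g, metric, scale)

  matched <- max.col(q, ties.method = "first")
  quality <- q[cbind(seq_len(n), matched)]
  label <- ifelse(quality >= pos_threshold, "positive",
                  ifelse(quality < neg_threshold, "negative", "ignore"))

  if (force_match) {
    claimed <- integer(0)
    for (j in seq_len(nrow(g))) {
      ord <- order(-q[, j], seq_len(n))
      pick <- ord[!(ord %in% claimed)][1L]
      if (is.na(pick)) pick <- ord[1L]  # more gts than anchors: reuse
      claimed <- c(claimed, pick)
      label[pick] <- "positive"
      matched[pick] <- j
      quality[pick] <- q[pick, j]
    }
  }
  matched[label == "negative"] <- NA_integer_
  out <- data.frame(label = factor(label, levels = label_levels()),
                    matched_gt = matched, quality = quality)
  class(out) <- c("match_result", class(out))
  out
}

label_levels <- function() c("positive", "negative", "ignore")

# anchors x gts similarity matrix; vectorized over anchors per gt
quality_matrix <- function(a, g, metric, scale) {
  n <- nrow(a)
  q <- matrix(NA_real_, n, nrow(g))
  for (j in seq_len(nrow(g)))
    q[, j] <- metric(a, g[j, , drop = FALSE], scale)
  q
}

#' Greedy non-maximum suppression under any registered metric
#'
#' Repeatedly keeps the highest-scoring remaining box and discards every
#' remaining box whose similarity to it is at or above `threshold`.
#' Score ties keep the lower index first. The kept set is returned in
#' descending-score order, and any two kept boxes have pairwise
#' similarity below `threshold`.
#'
#' With `metric_name = "tsd"` the suppression radius is governed by
#' center distance alone, so duplicates of a small object are removed by
#' proximity rather than overlap; negative TSD values are compared to
#' the threshold as-is.
#'
#' @param boxes_in a `boxes` matrix of detections.
#' @param scores numeric vector, one score per box.
#' @param metric_name a registered metric name.
#' @inheritParams tsd
#' @param threshold similarity at or above which a box is suppressed.
#' @return integer vector of kept row indices, descending by score.
#' @export
nms <- function(boxes_in, scores, metric_name = "iou", scale = NULL,
                threshold = 0.5) {
  b <- as_anchor_boxes(boxes_in)
  if (nrow(b) != length(scores))
    stop("boxes and scores lengths differ (", nrow(b), " vs ",
         length(scores), ")")
  metric <- box_metric(metric_name)
  ord <- order(-scores, seq_along(scores))
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (length(ord)) {
      sim <- metric(b[ord, , drop = FALSE], b[i, , drop = FALSE], scale)
      ord <- ord[sim < threshold]
    }
  }
  keep
}
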