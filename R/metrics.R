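#' Dataset scale statistic S
#'
#' The TSD metric standardizes the squared Chebyshev center distance by
#' `S`, the arithmetic mean area (in pixels squared) of all ground-truth
#' boxes in the dataset. `sqrt(S)` then plays the role of an average
#' side length. S is computed once per dataset and passed explicitly to
#' every TSD evaluation; it is never recomputed per pair.
#'
#' @param ground_truths a `boxes` matrix of all ground-truth boxes.
#' @return an object of class `"dataset_scale"`: a list with elements
#'   `S` (mean area, pixels^2) and `n_boxes`.
#' @examples
#' dataset_scale(boxes(c(0, 0), c(0, 0), c(4, 2), c(4, 2)))  # S = 10
#' @export
dataset_scale <- function(ground_truths) {
  gt <- as_boxes(ground_truths)
  structure(list(S = mean(box_area(gt)), n_boxes = nrow(gt)),
            class = "dataset_scale")
}

#' @export
print.dataset_scale <- function(x, ...) {
  cat(sprintf("dataset scale S = %g px^2 (mean area of %d ground truths; sqrt(S) = %g px)\n",
              x$S, x$n_boxes, sqrt(x$S)))
  invisible(x)
}

# accept a dataset_scale object or a bare positive number
scale_S <- function(scale) {
  S <- if (inherits(scale, "dataset_scale")) scale$S else scale
  if (is.null(S) || !is.numeric(S) || length(S) != 1L || !is.finite(S) || S <= 0)
    stop("dataset scale S must be a single positive finite number")
  S
}

#' Truncated structurally aware distance (TSD) metric
#'
#' Box similarity defined as
#' \deqn{\mathrm{TSD} = 1 - D_{Chess}^2(a, b) / S}
#' where \eqn{D_{Chess}} is the Chebyshev distance between the two box
#' centers and `S` the dataset's mean ground-truth area. The value lies
#' in \eqn{(-\infty, 1]}: exactly 1 iff the centers coincide, decreasing
#' without bound as the centers move apart. TSD depends only on the two
#' centers and S — it is insensitive to both boxes' widths and heights,
#' which is what makes it stable for small objects where a 1-pixel shift
#' collapses IoU.
#'
#' @param a,b `boxes` matrices, recycled row-wise.
#' @param scale a [dataset_scale()] object or a bare positive number S
#'   (pixels squared).
#' @return numeric vector of similarities in \eqn{(-\infty, 1]}.
#' @examples
#' S <- 100
#' tsd(boxes(0, 0, 32, 32), boxes(8, 8, 24, 24), S)   # concentric: 1
#' tsd(boxes(0, 0, 2, 2), boxes(5, 0, 7, 2), S)       # DChess 5: 0.75
#' @export
tsd <- function(a, b, scale) {
  S <- scale_S(scale)
  d <- chebyshev_center_distance(a, b)
  1 - d^2 / S
}

#' Intersection over union and its penalized variants
#'
#' `iou()` is overlap area over union area, in `[0, 1]`; 0 for disjoint
#' pairs, 1 iff the boxes are identical. The penalized variants subtract
#' a geometric penalty from IoU:
#' * `giou()`: IoU − |C \\ (A ∪ B)| / |C|, with C the smallest enclosing
#'   box; in `(-1, 1]`.
#' * `diou()`: IoU − d²/c², with d the Euclidean center distance and c
#'   the enclosing-box diagonal.
#' * `ciou()`: DIoU − αv, with aspect-ratio term
#'   v = (4/π²)(arctan(w_a/h_a) − arctan(w_b/h_b))² and
#'   α = v / ((1 − IoU) + v) (α taken as 0 when v = 0). The plain
#'   algebraic form is used, with no gradient-rescaling trick.
#'
#' All four are symmetric in their arguments.
#'
#' @inheritParams chebyshev_center_distance
#' @return numeric vector of similarities.
#' @export
iou <- function(a, b) {
  p <- recycle_boxes(a, b)
  inter <- intersection_area(p$a, p$b)
  inter / (box_area(p$a) + box_area(p$b) - inter)
}

enclosing_box <- function(a, b) {
  cbind(x_min = pmin(a[, "x_min"], b[, "x_min"]),
        y_min = pmin(a[, "y_min"], b[, "y_min"]),
        x_max = pmax(a[, "x_max"], b[, "x_max"]),
        y_max = pmax(a[, "y_max"], b[, "y_max"]))
}

#' @rdname iou
#' @export
giou <- function(a, b) {
  p <- recycle_boxes(a, b)
  u <- box_area(p$a) + box_area(p$b) - intersection_area(p$a, p$b)
  cbox <- enclosing_box(p$a, p$b)
  c_area <- unname((cbox[, "x_max"] - cbox[, "x_min"]) *
                   (cbox[, "y_max"] - cbox[, "y_min"]))
  iou(p$a, p$b) - (c_area - u) / c_area
}

#' @rdname iou
#' @export
diou <- function(a, b) {
  p <- recycle_boxes(a, b)
  cbox <- enclosing_box(p$a, p$b)
  c2 <- unname((cbox[, "x_max"] - cbox[, "x_min"])^2 +
               (cbox[, "y_max"] - cbox[, "y_min"])^2)
  iou(p$a, p$b) - euclidean_center_distance(p$a, p$b)^2 / c2
}

#' @rdname iou
#' @export
ciou <- function(a, b) {
  p <- recycle_boxes(a, b)
  wha <- box_wh(p$a); whb <- box_wh(p$b)
  v <- unname((4 / pi^2) *
    (atan(wha[, "w"] / wha[, "h"]) - atan(whb[, "w"] / whb[, "h"]))^2)
  i <- iou(p$a, p$b)
  alpha <- ifelse(v > 0, v / ((1 - i) + v), 0)
  diou(p$a, p$b) - alpha * v
}

#' Metric registry
#'
#' Label assignment, NMS and the simulation sweeps are metric-pluggable:
#' any registered metric can stand in wherever box similarity is needed.
#' Every metric function has signature `f(a, b, scale)`; the IoU family
#' ignores `scale`.
#'
#' @param name one of `"iou"`, `"giou"`, `"diou"`, `"ciou"`, `"tsd"`.
#' @return `box_metric()`: the metric function; `list_metrics()`: the
#'   registered metric names.
#' @export
box_metric <- function(name) {
  reg <- metric_registry()
  if (!name %in% names(reg))
    stop("unknown metric '", name, "'; registered: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' @rdname box_metric
#' @export
list_metrics <- function() names(metric_registry())

metric_registry <- function() {
  list(
    iou  = function(a, b, scale = NULL) iou(a, b),
    giou = function(a, b, scale = NULL) giou(a, b),
    diou = function(a, b, scale = NULL) diou(a, b),
    ciou = function(a, b, scale = NULL) ciou(a, b),
    tsd  = function(a, b, scale) tsd(a, b, scale)
  )
}
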