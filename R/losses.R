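#' Smooth L1 loss
#'
#' The piecewise regression loss used on box-encoding deltas:
#' `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise. Continuous with a
#' continuous first derivative at the knot `|x| = 1`.
#'
#' @param x numeric vector of finite residuals.
#' @return numeric vector of losses.
#' @export
smooth_l1 <- function(x) {
  if (!all(is.finite(x))) stop("smooth_l1 requires finite input")
  ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
}

#' Cosine of the structural angle between two intersecting boxes
#'
#' For intersecting boxes the TSD loss measures coincidence by the angle
#' theta opposite the center-to-center segment in the triangle with sides
#' `r1`, `r2` (the two circumradii) and `d` (the Euclidean center
#' distance), via the law of cosines:
#' \deqn{\cos\theta = (r_1^2 + r_2^2 - d^2) / (2 r_1 r_2)}
#' The raw value can exceed 1 for deeply overlapping pairs where
#' `d < |r1 - r2|` without box containment (e.g. a long thin box crossing
#' a small one); it is clamped to `[-1, 1]` so theta stays real and the
#' intersect-branch loss stays non-negative.
#'
#' @inheritParams chebyshev_center_distance
#' @return numeric vector of cosines in `[-1, 1]`.
#' @section Errors: Calling this on a pair that does not classify as
#'   `"intersect"` is a branch misuse and raises an error.
#' @export
cos_theta <- function(a, b) {
  p <- recycle_boxes(a, b)
  rel <- classify_relationship(p$a, p$b)
  if (any(rel != "intersect"))
    stop("cos_theta is defined only for intersecting box pairs (got ",
         paste(unique(as.character(rel[rel != "intersect"])), collapse = ", "), ")")
  raw_cos_theta(p$a, p$b)
}

raw_cos_theta <- function(a, b) {
  r1 <- box_circumradius(a)
  r2 <- box_circumradius(b)
  d <- euclidean_center_distance(a, b)
  pmin(1, pmax(-1, (r1^2 + r2^2 - d^2) / (2 * r1 * r2)))
}

#' TSD regression loss with branch breakdown
#'
#' The truncated structurally aware distance loss selects one of three
#' penalty forms by the structural relationship of the pair:
#' \describe{
#'   \item{separated}{\eqn{D_{Chess}^2 / S} — squared Chebyshev center
#'     distance standardized by the dataset scale; unbounded above,
#'     strictly increasing with center distance.}
#'   \item{intersect}{\eqn{1 - \cos\theta} with theta from
#'     [cos_theta()]; in `[0, 2]`.}
#'   \item{contain}{\eqn{1 - e^{-|r_1 - r_2|}} — penalizes the mismatch
#'     of the two circumradii; in `[0, 1)`, zero iff the radii agree.}
#' }
#' Identical boxes classify as contained with `r1 = r2`, so a perfect
#' prediction has loss exactly 0. The truncation between branches is
#' intentional: the loss is not continuous across relationship
#' transitions.
#'
#' @inheritParams tsd
#' @param normalize_contain_radius if `TRUE`, the contain-branch exponent
#'   uses `|r1 - r2| / sqrt(S)` instead of raw pixels, making that branch
#'   dimensionless like the others. Default `FALSE`: the exponent is kept
#'   in raw pixels, the loss's canonical dimensionful form.
#' @return a data frame with one row per pair and columns
#'   \describe{
#'     \item{value}{the loss, always >= 0}
#'     \item{branch}{factor, the selected relationship branch}
#'     \item{x}{the branch's independent variable: \eqn{D_{Chess}^2/S}
#'       (separated), theta in radians (intersect), or `|r1 - r2|`
#'       (contain)}
#'     \item{gradient}{the closed-form derivative of the branch loss with
#'       respect to `x`: 1, `sin(x)`, or `exp(-x)`}
#'   }
#' @examples
#' S <- 100
#' tsd_loss(boxes(0, 0, 8, 8), boxes(0, 0, 8, 8), S)       # contain, 0
#' tsd_loss(boxes(0, 0, 2, 2), boxes(10, 0, 12, 2), S)     # separated, 1
#' @export
tsd_loss <- function(a, b, scale, normalize_contain_radius = FALSE) {
  S <- scale_S(scale)
  p <- recycle_boxes(a, b)
  rel <- classify_relationship(p$a, p$b)
  n <- nrow(p$a)
  x <- value <- grad <- numeric(n)

  sep <- rel == "separated"
  if (any(sep)) {
    x[sep] <- chebyshev_center_distance(p$a[sep, , drop = FALSE],
                                        p$b[sep, , drop = FALSE])^2 / S
    value[sep] <- x[sep]
    grad[sep] <- 1
  }
  ints <- rel == "intersect"
  if (any(ints)) {
    ct <- raw_cos_theta(p$a[ints, , drop = FALSE], p$b[ints, , drop = FALSE])
    x[ints] <- acos(ct)
    value[ints] <- 1 - ct
    grad[ints] <- sin(x[ints])
  }
  con <- rel == "contain"
  if (any(con)) {
    dr <- abs(box_circumradius(p$a[con, , drop = FALSE]) -
              box_circumradius(p$b[con, , drop = FALSE]))
    if (normalize_contain_radius) dr <- dr / sqrt(S)
    x[con] <- dr
    value[con] <- 1 - exp(-dr)
    grad[con] <- exp(-dr)
  }
  data.frame(value = value, branch = rel, x = x, gradient = grad)
}

#' Closed-form TSD loss branch gradients
#'
#' Derivative of each branch of the TSD loss with respect to its
#' independent variable `x`: 1 for separated (`x = DChess^2/S >= 0`),
#' `sin(x)` for intersect (`x = theta` in `[0, pi]`), `exp(-x)` for
#' contain (`x = |r1 - r2| >= 0`). Every branch gradient is bounded above
#' by 1, which caps the step size any single pair can contribute during
#' regression.
#'
#' @param branch character or factor vector of branch names
#'   (`"separated"`, `"intersect"`, `"contain"`), recycled against `x`.
#' @param x numeric vector of branch variables, each within its branch's
#'   domain.
#' @return numeric vector of gradients.
#' @export
tsd_loss_gradient <- function(branch, x) {
  branch <- as.character(branch)
  if (!all(branch %in% relationship_levels()))
    stop("unknown branch; expected one of ",
         paste(relationship_levels(), collapse = ", "))
  n <- max(length(branch), length(x))
  branch <- rep_len(branch, n)
  x <- rep_len(x, n)
  if (any(!is.finite(x))) stop("branch variable x must be finite")
  if (any(x < 0)) stop("branch variable x must be >= 0")
  if (any(branch == "intersect" & x > pi))
    stop("intersect branch requires x = theta in [0, pi]")
  out <- numeric(n)
  out[branch == "separated"] <- 1
  out[branch == "intersect"] <- sin(x[branch == "intersect"])
  out[branch == "contain"] <- exp(-x[branch == "contain"])
  out
}

#' Focal loss for binary anchor classification
#'
#' Cross-entropy reweighted to down-weight easy examples:
#' \eqn{-\alpha_t (1 - p_t)^\gamma \log p_t}, with `p_t = p` and
#' `alpha_t = alpha` for positives, `p_t = 1 - p` and
#' `alpha_t = 1 - alpha` for negatives. With `gamma = 0` and
#' `alpha = 0.5` it reduces to half the cross-entropy. Defaults are the
#' setting found best for dense small-pest classification
#' (`alpha = 0.5`, `gamma = 2`).
#'
#' @param p numeric vector of predicted foreground probabilities,
#'   strictly inside (0, 1).
#' @param is_positive logical vector: is each anchor a positive example?
#' @param alpha class-balance weight in `[0, 1]` given to positives.
#' @param gamma focusing exponent, `>= 0`.
#' @return numeric vector of per-anchor losses.
#' @export
focal_loss <- function(p, is_positive, alpha = 0.5, gamma = 2) {
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0, 1)")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  pt <- ifelse(is_positive, p, 1 - p)
  at <- ifelse(is_positive, alpha, 1 - alpha)
  -at * (1 - pt)^gamma * log(pt)
}

#' Image-level focal loss total
#'
#' Sums the per-anchor focal losses and normalizes by the number of
#' anchors assigned to a ground truth (the positives) rather than the
#' total anchor count: with the vast majority of anchors easy negatives,
#' total-anchor normalization would wash the loss out.
#'
#' @param p per-anchor foreground probabilities in (0, 1).
#' @param labels per-anchor labels as returned by [assign_labels()]
#'   (`"positive"`, `"negative"`, `"ignore"`); ignored anchors contribute
#'   nothing.
#' @inheritParams focal_loss
#' @return a single number: total focal loss / number of positives.
#' @export
focal_loss_total <- function(p, labels, alpha = 0.5, gamma = 2) {
  labels <- as.character(labels)
  if (length(p) != length(labels)) stop("p and labels lengths differ")
  keep <- labels != "ignore"
  n_pos <- sum(labels == "positive")
  if (n_pos == 0L) stop("no positive anchors to normalize by")
  sum(focal_loss(p[keep], labels[keep] == "positive", alpha, gamma)) / n_pos
}

#' Mean regression loss over a batch of box pairs
#'
#' Aggregates a per-pair regression loss over aligned prediction /
#' ground-truth box sets with an unweighted arithmetic mean.
#' `loss_name = "tsd"` uses the branch-structured [tsd_loss()];
#' `"smooth_l1"` applies [smooth_l1()] to the standard 4-coordinate
#' encoding deltas `(dx, dy, dw, dh)` of each pair (summed per pair);
#' the IoU-family names use `1 - metric`.
#'
#' @param pred,gt `boxes` matrices of equal row count (pairs are aligned
#'   row-wise).
#' @inheritParams tsd
#' @param loss_name one of [list_losses()].
#' @return a single non-negative number.
#' @export
batch_regression_loss <- function(pred, gt, scale = NULL, loss_name = "tsd") {
  pred <- as_boxes(pred); gt <- as_boxes(gt)
  if (nrow(pred) != nrow(gt))
    stop("pred and gt must have the same number of boxes")
  mean(box_loss(loss_name)(pred, gt, scale))
}

#' Loss registry
#'
#' Per-pair regression losses keyed by name, each with signature
#' `f(pred, gt, scale)` returning one loss per pair.
#'
#' @param name one of `"tsd"`, `"smooth_l1"`, `"iou"`, `"giou"`,
#'   `"diou"`, `"ciou"`.
#' @return `box_loss()`: the loss function; `list_losses()`: registered
#'   names.
#' @export
box_loss <- function(name) {
  reg <- loss_registry()
  if (!name %in% names(reg))
    stop("unknown loss '", name, "'; registered: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' @rdname box_loss
#' @export
list_losses <- function() names(loss_registry())

loss_registry <- function() {
  one_minus <- function(metric) function(pred, gt, scale = NULL) 1 - metric(pred, gt)
  list(
    tsd = function(pred, gt, scale) tsd_loss(pred, gt, scale)$value,
    smooth_l1 = function(pred, gt, scale = NULL) {
      d <- encode_deltas(pred, gt)
      rowSums(matrix(smooth_l1(d), ncol = 4L))
    },
    iou = one_minus(iou), giou = one_minus(giou),
    diou = one_minus(diou), ciou = one_minus(ciou)
  )
}

# standard (dx, dy, dw, dh) box encoding of gt relative to pred
encode_deltas <- function(pred, gt) {
  p <- recycle_boxes(pred, gt)
  cp <- box_center(p$a); cg <- box_center(p$b)
  wp <- box_wh(p$a); wg <- box_wh(p$b)
  cbind(dx = (cg[, "cx"] - cp[, "cx"]) / wp[, "w"],
        dy = (cg[, "cy"] - cp[, "cy"]) / wp[, "h"],
        dw = log(wg[, "w"] / wp[, "w"]),
        dh = log(wg[, "h"] / wp[, "h"]))
}
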