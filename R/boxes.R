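#' Construct a set of axis-aligned bounding boxes
#'
#' Boxes are represented as a numeric matrix with one row per box and
#' columns `x_min`, `y_min`, `x_max`, `y_max`, in continuous pixel
#' coordinates (corner convention, no half-open pixel-index semantics).
#' Every geometric and metric function in the package accepts this matrix
#' form and is vectorized over rows.
#'
#' @param x_min,y_min,x_max,y_max numeric vectors of corner coordinates,
#'   recycled to a common length.
#' @return a numeric matrix of class `"boxes"` with columns
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @details Zero-area boxes are rejected: widths and heights must be
#'   strictly positive, since circumradii and IoU denominators degenerate
#'   at zero area. All coordinates must be finite.
#' @examples
#' b <- boxes(0, 0, c(2, 4), c(2, 4))
#' box_center(b)
#' @export
boxes <- function(x_min, y_min, x_max, y_max) {
  m <- cbind(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  storage.mode(m) <- "double"
  validate_boxes(m)
}

#' Coerce to a boxes matrix
#'
#' @param x a `boxes` matrix, a plain 4-column numeric matrix, a numeric
#'   vector of length 4, or a data frame with columns
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @return a validated `boxes` matrix.
#' @export
as_boxes <- function(x) {
  if (inherits(x, "boxes")) return(validate_boxes(unclass(x)))
  if (is.data.frame(x)) {
    need <- c("x_min", "y_min", "x_max", "y_max")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("missing box columns: ", paste(miss, collapse = ", "))
    return(boxes(x$x_min, x$y_min, x$x_max, x$y_max))
  }
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 4L)
    x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || ncol(x) != 4L)
    stop("cannot interpret input as boxes (need a 4-column matrix)")
  boxes(x[, 1L], x[, 2L], x[, 3L], x[, 4L])
}

validate_boxes <- function(m) {
  if (!is.matrix(m) || ncol(m) != 4L || nrow(m) < 1L)
    stop("boxes must be a non-empty 4-column numeric matrix")
  if (!all(is.finite(m)))
    stop("box coordinates must all be finite")
  w <- m[, 3L] - m[, 1L]
  h <- m[, 4L] - m[, 2L]
  bad <- which(w <= 0 | h <= 0)
  if (length(bad))
    stop("boxes must have strictly positive width and height (rows ",
         paste(utils::head(bad, 5L), collapse = ", "), ")")
  colnames(m) <- c("x_min", "y_min", "x_max", "y_max")
  class(m) <- c("boxes", class(matrix()))
  m
}

# recycle two box matrices to a common number of rows (1 -> n only)
recycle_boxes <- function(a, b) {
  a <- as_boxes(a); b <- as_boxes(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == nb) return(list(a = a, b = b))
  if (na == 1L) return(list(a = a[rep(1L, nb), , drop = FALSE], b = b))
  if (nb == 1L) return(list(a = a, b = b[rep(1L, na), , drop = FALSE]))
  stop("box sets have incompatible row counts (", na, " vs ", nb, ")")
}

#' Box centers, sizes and areas
#'
#' @param b a `boxes` matrix (see [boxes()]).
#' @return `box_center()`: an n x 2 matrix of center coordinates
#'   (`cx`, `cy`); `box_wh()`: an n x 2 matrix of widths and heights;
#'   `box_area()`: a numeric vector of areas in pixels squared.
#' @export
box_center <- function(b) {
  b <- as_boxes(b)
  cbind(cx = unname((b[, "x_min"] + b[, "x_max"]) / 2),
        cy = unname((b[, "y_min"] + b[, "y_max"]) / 2))
}

#' @rdname box_center
#' @export
box_wh <- function(b) {
  b <- as_boxes(b)
  cbind(w = unname(b[, "x_max"] - b[, "x_min"]),
        h = unname(b[, "y_max"] - b[, "y_min"]))
}

#' @rdname box_center
#' @export
box_area <- function(b) {
  wh <- box_wh(b)
  unname(wh[, "w"] * wh[, "h"])
}

#' Circumcircle radius of a box
#'
#' Radius of the circle through a box's four corners: half the diagonal,
#' \eqn{r = \sqrt{w^2 + h^2} / 2}. This is the `r` entering the
#' containment branch of the TSD loss.
#'
#' @inheritParams box_center
#' @return numeric vector of radii in pixels.
#' @export
box_circumradius <- function(b) {
  wh <- box_wh(b)
  unname(sqrt(wh[, "w"]^2 + wh[, "h"]^2) / 2)
}

#' Center-to-center distances between boxes
#'
#' `chebyshev_center_distance()` is the L-infinity distance between the
#' two box centers, \eqn{\max(|x_1 - x_2|, |y_1 - y_2|)} — the distance
#' that the TSD metric standardizes. `euclidean_center_distance()` is the
#' usual L2 distance, the `d` of the law-of-cosines term in the
#' intersect branch of the TSD loss. Both are symmetric, zero iff the
#' centers coincide, and satisfy Chebyshev <= Euclidean.
#'
#' @param a,b `boxes` matrices, recycled row-wise to a common length.
#' @return numeric vector of distances in pixels.
#' @export
chebyshev_center_distance <- function(a, b) {
  p <- recycle_boxes(a, b)
  ca <- box_center(p$a); cb <- box_center(p$b)
  unname(pmax(abs(ca[, "cx"] - cb[, "cx"]), abs(ca[, "cy"] - cb[, "cy"])))
}

#' @rdname chebyshev_center_distance
#' @export
euclidean_center_distance <- function(a, b) {
  p <- recycle_boxes(a, b)
  ca <- box_center(p$a); cb <- box_center(p$b)
  unname(sqrt((ca[, "cx"] - cb[, "cx"])^2 + (ca[, "cy"] - cb[, "cy"])^2))
}

#' Rectangle intersection area
#'
#' Area of the overlap rectangle; 0 when the boxes are disjoint or touch
#' only along an edge or corner.
#'
#' @inheritParams chebyshev_center_distance
#' @return numeric vector of areas in pixels squared.
#' @export
intersection_area <- function(a, b) {
  p <- recycle_boxes(a, b)
  iw <- pmin(p$a[, "x_max"], p$b[, "x_max"]) - pmax(p$a[, "x_min"], p$b[, "x_min"])
  ih <- pmin(p$a[, "y_max"], p$b[, "y_max"]) - pmax(p$a[, "y_min"], p$b[, "y_min"])
  unname(pmax(iw, 0) * pmax(ih, 0))
}

#' Structural relationship between two boxes
#'
#' Classifies each ordered pair into the trichotomy that selects the TSD
#' loss branch: `"contain"` when all four corners of one box lie inside
#' or on the boundary of the other (identical boxes count as contained,
#' so a perfect prediction lands in the only branch whose loss is zero);
#' `"intersect"` when the overlap area is positive but neither contains
#' the other; `"separated"` otherwise, including boxes touching only at
#' an edge or corner (where IoU already degenerates to 0). The
#' classification is symmetric.
#'
#' @inheritParams chebyshev_center_distance
#' @return a factor with levels `"separated"`, `"intersect"`, `"contain"`.
#' @export
classify_relationship <- function(a, b) {
  p <- recycle_boxes(a, b)
  a <- p$a; b <- p$b
  a_in_b <- a[, "x_min"] >= b[, "x_min"] & a[, "y_min"] >= b[, "y_min"] &
            a[, "x_max"] <= b[, "x_max"] & a[, "y_max"] <= b[, "y_max"]
  b_in_a <- b[, "x_min"] >= a[, "x_min"] & b[, "y_min"] >= a[, "y_min"] &
            b[, "x_max"] <= a[, "x_max"] & b[, "y_max"] <= a[, "y_max"]
  contain <- a_in_b | b_in_a
  inter <- intersection_area(a, b) > 0 & !contain
  out <- rep("separated", nrow(a))
  out[inter] <- "intersect"
  out[contain] <- "contain"
  factor(out, levels = relationship_levels())
}

relationship_levels <- function() c("separated", "intersect", "contain")
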