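test_that("smooth L1 matches its piecewise definition and is C1 at the knot", {
  expect_equal(smooth_l1(0), 0)
  expect_equal(smooth_l1(3), 2.5)
  expect_equal(smooth_l1(-3), 2.5)
  # value continuity at |x| = 1: both pieces give 0.5
  expect_equal(smooth_l1(1), 0.5)
  eps <- 1e-8
  expect_equal(smooth_l1(1 - eps), smooth_l1(1 + eps), tolerance = 1e-6)
  # derivative continuity: slope -> 1 from both sides
  slope <- function(x) (smooth_l1(x + eps) - smooth_l1(x - eps)) / (2 * eps)
  expect_equal(slope(1 - 1e-5), slope(1 + 1e-5), tolerance = 1e-4)
  expect_error(smooth_l1(NaN), "finite")
})

test_that("cos_theta matches the law of cosines and clamps", {
  # congruent intersecting squares with d = r1 = r2: equilateral triangle
  a <- boxes(0, 0, 4, 4); b <- boxes(2, 2, 6, 6)
  expect_equal(cos_theta(a, b), 0.5)
  # d -> 0 with r1 = r2 would give cos -> 1 (near-coincident intersecting pair)
  a2 <- boxes(0, 0, 4, 4); b2 <- boxes(1e-9, -1e-9, 4 + 1e-9, 4 - 1e-9)
  expect_equal(cos_theta(a2, b2), 1, tolerance = 1e-6)
  # thin box crossing a small one: raw value > 1, clamped to 1
  thin <- boxes(-50, 0, 50, 2); small <- boxes(0.5, -1, 1.5, 1)
  expect_equal(as.character(classify_relationship(thin, small)), "intersect")
  expect_identical(cos_theta(thin, small), 1)
  # branch misuse errors
  expect_error(cos_theta(boxes(0, 0, 2, 2), boxes(5, 5, 7, 7)), "intersect")
  expect_error(cos_theta(boxes(0, 0, 9, 9), boxes(1, 1, 2, 2)), "intersect")
})

test_that("tsd_loss selects branches and matches hand-computed values", {
  S <- 100
  # identical boxes: contain branch, loss exactly 0
  ident <- tsd_loss(boxes(3, 4, 9, 10), boxes(3, 4, 9, 10), S)
  expect_equal(as.character(ident$branch), "contain")
  expect_identical(ident$value, 0)
  # disjoint, Chebyshev 10, S 100 -> 1
  sep <- tsd_loss(boxes(0, 0, 2, 2), boxes(10, 0, 12, 2), S)
  expect_equal(as.character(sep$branch), "separated")
  expect_equal(sep$value, 1)
  # concentric nested with r1 = 5, r2 = 3 -> 1 - exp(-2)
  con <- tsd_loss(boxes(-4, -3, 4, 3), boxes(-2.4, -1.8, 2.4, 1.8), S)
  expect_equal(as.character(con$branch), "contain")
  expect_equal(con$value, 1 - exp(-2))
  # intersect: 1 - cos(theta)
  int <- tsd_loss(boxes(0, 0, 4, 4), boxes(2, 2, 6, 6), S)
  expect_equal(as.character(int$branch), "intersect")
  expect_equal(int$value, 0.5)
  # contain-branch normalization option divides the exponent by sqrt(S)
  con_n <- tsd_loss(boxes(-4, -3, 4, 3), boxes(-2.4, -1.8, 2.4, 1.8), S,
                    normalize_contain_radius = TRUE)
  expect_equal(con_n$value, 1 - exp(-2 / sqrt(S)))
})

test_that("tsd_loss is non-negative and branch-consistent on random pairs", {
  set.seed(91)
  a <- random_boxes(10000, span = 64, side_range = c(1, 32))
  b <- random_boxes(10000, span = 64, side_range = c(1, 32))
  lb <- tsd_loss(a, b, 100)
  expect_true(all(lb$value >= 0))
  expect_equal(lb$branch, classify_relationship(a, b))
  expect_true(all(table(lb$branch) > 0))  # all three branches exercised
})

test_that("closed-form branch gradients match central finite differences", {
  forms <- list(separated = function(x) x,
                intersect = function(x) 1 - cos(x),
                contain = function(x) 1 - exp(-x))
  domains <- list(separated = seq(0.01, 10, length.out = 100),
                  intersect = seq(0.01, pi - 0.01, length.out = 100),
                  contain = seq(0.01, 10, length.out = 100))
  h <- 1e-6
  for (br in names(forms)) {
    x <- domains[[br]]
    fd <- (forms[[br]](x + h) - forms[[br]](x - h)) / (2 * h)
    g <- tsd_loss_gradient(br, x)
    expect_equal(g, fd, tolerance = 1e-6, info = br)
  }
})

test_that("branch gradients are bounded by 1 and domain-checked", {
  x_int <- seq(0, pi, length.out = 1000)
  expect_true(all(abs(tsd_loss_gradient("intersect", x_int)) <= 1))
  x_con <- seq(0.01, 10, length.out = 1000)
  g_con <- tsd_loss_gradient("contain", x_con)
  expect_true(all(g_con > 0 & g_con <= 1))
  expect_true(all(tsd_loss_gradient("separated", runif(100, 0, 50)) == 1))
  expect_error(tsd_loss_gradient("intersect", 4), "0, pi")
  expect_error(tsd_loss_gradient("separated", -1), ">= 0")
  expect_error(tsd_loss_gradient("overlap", 1), "unknown branch")
})

test_that("tsd_loss gradients in the breakdown agree with finite differences of the pairwise loss", {
  S <- 64
  # separated: move the second box away and differentiate w.r.t. x = D^2/S
  d <- 10; h <- 1e-4
  val <- function(d) tsd_loss(boxes(0, 0, 2, 2), boxes(d, 0, d + 2, 2), S)$value
  x_of <- function(d) d^2 / S
  fd <- (val(d + h) - val(d - h)) / (x_of(d + h) - x_of(d - h))
  expect_equal(tsd_loss(boxes(0, 0, 2, 2), boxes(d, 0, d + 2, 2), S)$gradient,
               fd, tolerance = 1e-6)
})

test_that("branch losses are monotone in their structural variable", {
  S <- 100
  # separated: strictly increasing in Chebyshev distance
  ds <- seq(5, 40, by = 5)
  sep_vals <- tsd_loss(boxes(0, 0, 2, 2), boxes(ds, 0, ds + 2, 2), S)$value
  expect_true(all(diff(sep_vals) > 0))
  # contain: strictly increasing in |r1 - r2|, zero iff equal radii
  inner_sides <- c(8, 6, 4, 2)
  outer <- boxes(-5, -5, 5, 5)
  con_vals <- sapply(inner_sides, function(s)
    tsd_loss(outer, boxes(-s / 2, -s / 2, s / 2, s / 2), S)$value)
  expect_true(all(diff(con_vals) > 0))
  expect_identical(tsd_loss(outer, outer, S)$value, 0)
  # intersect: 1 - cos(theta) non-decreasing in d at fixed radii
  offs <- seq(0.5, 3.5, by = 0.5)
  int_vals <- tsd_loss(boxes(0, 0, 4, 4), boxes(offs, offs, offs + 4, offs + 4), S)$value
  expect_true(all(diff(int_vals) >= 0))
})

test_that("focal loss follows the standard alpha-gamma form", {
  # gamma 0, alpha 0.5: half cross-entropy
  expect_equal(focal_loss(0.5, TRUE, alpha = 0.5, gamma = 0), 0.5 * log(2))
  # confident correct prediction -> loss -> 0
  expect_lt(focal_loss(1 - 1e-9, TRUE), 1e-6)
  # focusing factor (1 - 0.9)^2 = 0.01
  ce <- focal_loss(0.9, TRUE, alpha = 0.5, gamma = 0)
  fl <- focal_loss(0.9, TRUE, alpha = 0.5, gamma = 2)
  expect_equal(fl / ce, 0.01)
  # negatives use 1 - p and 1 - alpha
  expect_equal(focal_loss(0.2, FALSE, alpha = 0.25, gamma = 0),
               -0.75 * log(0.8))
  expect_error(focal_loss(1, TRUE), "strictly in")
  expect_error(focal_loss(0.5, TRUE, alpha = 2), "alpha")
})

test_that("image-level focal loss normalizes by the positive-anchor count", {
  p <- c(0.9, 0.8, 0.1, 0.2, 0.5)
  labels <- c("positive", "positive", "negative", "negative", "ignore")
  per <- focal_loss(p[1:4], c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(focal_loss_total(p, labels), sum(per) / 2)
  expect_error(focal_loss_total(p, rep("negative", 5)), "no positive")
})

test_that("batch losses aggregate by unweighted mean across registered losses", {
  S <- 100
  a <- boxes(c(0, 0), c(0, 0), c(2, 2), c(2, 2))
  # identical pairs: tsd loss 0
  expect_equal(batch_regression_loss(a, a, S, "tsd"), 0)
  # one pair equals the single-pair loss
  p1 <- boxes(0, 0, 2, 2); g1 <- boxes(10, 0, 12, 2)
  expect_equal(batch_regression_loss(p1, g1, S, "tsd"),
               tsd_loss(p1, g1, S)$value)
  # two disjoint pairs with branch values 0.5 and 1.5 average to 1
  pred <- boxes(c(0, 0), c(0, 0), c(2, 2), c(2, 2))
  gt <- boxes(c(sqrt(50), sqrt(150)), c(0, 0),
              c(sqrt(50) + 2, sqrt(150) + 2), c(2, 2))
  expect_equal(batch_regression_loss(pred, gt, S, "tsd"), 1)
  # smooth_l1 on encoding deltas: identical boxes -> 0
  expect_equal(batch_regression_loss(a, a, S, "smooth_l1"), 0)
  # 1 - metric family
  expect_equal(batch_regression_loss(p1, g1, S, "iou"), 1)
  expect_equal(batch_regression_loss(a, a, S, "giou"), 0)
  expect_error(batch_regression_loss(p1, boxes(c(0, 0), c(0, 0), c(1, 1), c(1, 1)), S),
               "same number")
  expect_error(box_loss("hinge"), "unknown loss")
})
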