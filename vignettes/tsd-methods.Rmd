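---
title: "Structurally aware box distances for dense small-object scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structurally aware box distances for dense small-object scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsdbox)
```

## Why not IoU for small objects

In anchor-based detection, box similarity drives three decisions:
which anchors train as positives (label assignment), which detections
survive deduplication (NMS), and how far a predicted box is from its
target (regression loss). IoU — overlap over union — serves all three
well for medium and large objects but has three structural failures in
the small-object regime:

1. **Size sensitivity.** A fixed localization error costs a small box
   far more IoU than a large one. Shift a 4×4 box by (1, 1) and IoU
   falls from 1 to about 0.39; shift a 32×32 box the same way and it
   only falls to about 0.88.
2. **Saturation when disjoint.** IoU is identically 0 for every
   non-overlapping pair, so a nearly-touching anchor and a distant one
   look the same.
3. **Blindness inside containment.** Any box nested inside another at
   fixed sizes has the same IoU regardless of where it sits.

For objects under ~32 px — insects in trap images being the motivating
case, with the added difficulty that they aggregate densely — failure 1
means few anchors clear the positive threshold, and failures 2–3 starve
assignment and NMS of any gradient of similarity to act on.

## The TSD metric

TSD replaces overlap with a standardized center distance:

$$\mathrm{TSD}(b, b_{gt}) = 1 - \frac{D_{Chess}^2(b, b_{gt})}{S},
\qquad D_{Chess} = \max(|x_1 - x_2|,\, |y_1 - y_2|),$$

with $(x_i, y_i)$ the box centers and $S$ the arithmetic mean area of
all ground-truth boxes in the dataset. Properties that the test suite
asserts:

* range $(-\infty, 1]$, with 1 exactly iff the centers coincide;
* independent of both boxes' widths and heights at fixed centers, so
  deviation curves for different box sizes coincide *exactly*, not
  approximately;
* strictly decreasing in center distance, including across the
  disjoint regime where IoU is flat at 0 and inside containment where
  IoU is constant.

**Why $S$ is an area.** $S$ is described both as an average area and,
loosely, as an average side length. Since the squared distance is
divided by it, only the area reading is dimensionally coherent:
$D^2/S$ is then dimensionless and $\sqrt S$ plays the side-length
role. $S$ is computed once per dataset with `dataset_scale()` and
passed explicitly everywhere — determinism matters more than
convenience here, and recomputing it per pair would silently change the
metric as data flows through. Whether to compute it on a training split
or a whole dataset is the caller's choice; the package simply uses
whatever ground-truth collection it is given.

## The TSD loss

`1 - TSD` would be a usable loss but treats every geometric
configuration identically. The TSD loss instead picks a penalty by the
structural relationship of the pair — the trichotomy returned by
`classify_relationship()`:

| branch | loss | variable $x$ | gradient $dL/dx$ |
|---|---|---|---|
| separated | $D_{Chess}^2 / S$ | $D_{Chess}^2/S$ | $1$ |
| intersect | $1 - \cos\theta$ | $\theta$ | $\sin x \le 1$ |
| contain | $1 - e^{-\lvert r_1 - r_2\rvert}$ | $\lvert r_1 - r_2\rvert$ | $e^{-x} \le 1$ |

$\theta$ comes from the law of cosines on the triangle with sides
$r_1$, $r_2$ (circumcircle radii, i.e. half-diagonals) and $d$ (the
Euclidean center distance); the contain branch penalizes the radius
mismatch, which is zero exactly for a perfect prediction. All three
gradients are bounded by 1, so no single pair can dominate a batch
update the way an unbounded IoU-style penalty can.

```{r}
S <- 100
tsd_loss(boxes(0, 0, 4, 4), boxes(2, 2, 6, 6), S)      # intersecting
tsd_loss(boxes(-5, -5, 5, 5), boxes(-2, -2, 2, 2), S)  # nested
```

### Boundary conventions

The branch boundaries are genuinely open choices; the package fixes
them as follows and tests them explicitly:

* **Touching boxes** (shared edge or corner, zero overlap area) are
  *separated*: IoU already degenerates to 0 there, and the separated
  branch remains well defined and continuous in the center distance.
* **Identical boxes** (mutual containment) are *contained*: the contain
  branch is the only one that returns 0 for a perfect prediction.
* **$\cos\theta$ is clamped to $[-1, 1]$.** Deep overlap without
  containment (a long thin box crossing a small one) can push the raw
  law-of-cosines value above 1 because $d < |r_1 - r_2|$; clamping
  keeps $\theta$ real and the loss non-negative.
* **The contain exponent is raw pixels** by default, exactly as the
  loss is defined, although that makes the branch dimensionful; setting
  `normalize_contain_radius = TRUE` in `tsd_loss()` divides by
  $\sqrt S$ for a dimensionless variant.
* **Cross-branch discontinuity is accepted.** The truncation is the
  design: tests assert branch values, not continuity at relationship
  transitions. Likewise the separated branch is unbounded above while
  the others are bounded by 2 and 1; no rebalancing is applied.
* The loss is computed **directly on box coordinates**, not on encoded
  regression deltas; `smooth_l1` on the standard 4-delta encoding is
  available alongside for comparison.

## Assignment and NMS

`assign_labels()` and `nms()` are metric-pluggable: any registered
metric (`iou`, `giou`, `diou`, `ciou`, `tsd`) can serve as the
similarity. Thresholds default to the classic positive 0.7 / negative
0.3 / NMS 0.5 convention. On the TSD scale these defaults inherit
IoU's "1 = perfect" calibration but are otherwise **unvalidated
conventions** — they are exposed as parameters precisely so users can
tune them. TSD values below 0 are compared to thresholds as-is; there
is no flooring, which preserves the metric's ability to rank disjoint
candidates in NMS.

Force-matching (on by default) gives every ground truth its
best-quality anchor as a positive even when no anchor clears the
threshold — the rescue that matters most for small objects. When two
ground truths share a best anchor, each ground truth in input order
claims its best *not-yet-claimed* anchor (quality-ranked, ties to the
lowest anchor index). This is deterministic and guarantees at least one
positive per ground truth whenever anchors are at least as numerous as
ground truths; with fewer anchors than ground truths the guarantee is
geometrically impossible and the last claimant wins.

Anchors follow the area-preserving convention
($w = s\sqrt{\rho}$, $h = s/\sqrt{\rho}$) with default sizes
$(8, 16, 32, 64, 128)$ and ratios $(0.5, 1, 2)$, unclipped by default
as in standard region-proposal practice.

NMS is the standard pairwise greedy form (highest score kept, too-close
survivors discarded), with score ties broken by lower index for
determinism.

## The synthetic scene generator

`make_scene()` emulates the geometry of a dense small-object dataset —
the only aspects of such data these analyses need:

* ground-truth sides uniform in 4–16 px by default (the sub-32-px
  regime), centers uniform with boxes kept inside a 512×512 image;
* detections derived from ground truths by Gaussian center jitter
  (default sd 1 px per coordinate — a realistic localization error for
  boxes this size), mild log-normal size jitter (sd 0.05 in log space),
  and duplicate detections at rate 0.1 to give NMS something to do;
* scores `exp(-jitter/side)`, a monotone function of localization
  error chosen for determinism, not realism.

Everything is seed-driven and bit-reproducible, and the caller's RNG
state is untouched. What the generator deliberately does **not**
emulate: pixel appearance, class imbalance across 20+ categories,
occlusion, and the correlated errors of a real detector's score head.
Passing tests on these scenes therefore validates the *geometry* of the
metrics, losses, assignment and NMS — not end-to-end detection quality
on real imagery, which requires training a detector on real data.

## Deviation curves

`deviation_curve()` reproduces the size-sensitivity analysis: box A of
side $s$ fixed at the origin, box B drawn away along A's diagonal.
"Deviation $k$" is parameterized as the center offset vector $(k, k)$,
so the Chebyshev distance is exactly $k$ and the TSD curve is exactly
$1 - k^2/S$ at integral pixels — making the coincidence claim testable
with `identical()`, not a tolerance. The four-curve comparison is read
as four sizes of A (8, 16, 32, 64 px) with B at half side by default.
Note that with `side_ratio = 0.5` the IoU curve *starts* at the
containment value $0.25$ and stays flat while B remains inside A; the
start-at-1 and one-pixel-drop comparisons are therefore made at
`side_ratio = 1` (equal-size shifted squares), where they are
well-defined.

```{r}
curves <- do.call(rbind, lapply(c(8, 16, 32, 64), deviation_curve,
                                scale = 100, metric_name = "tsd",
                                max_dev = 5))
unique(split(curves$value, curves$box_side))  # one distinct curve
```

## Numerical and testing choices

* Coordinates are continuous corner coordinates; no half-open
  pixel-index convention, since every formula is geometric.
* Zero-area boxes are rejected at construction (circumradius and IoU
  denominators degenerate); all coordinates must be finite.
* The analytic IoU is cross-checked against an independent rasterized
  oracle: the smallest region enclosing both boxes is covered by a
  1000×1000 grid of cell midpoints and cells are counted per box
  (counts factor per axis for axis-aligned boxes), with 2% agreement
  required. Greedy NMS is cross-checked index-by-index against a
  brute-force similarity-matrix implementation on 100 seeded scenes of
  50 boxes.
* Closed-form branch gradients are checked against central finite
  differences of the branch forms at 100 interior points per branch at
  relative tolerance $10^{-6}$.
* Property sweeps use 10,000 seeded random pairs for range, trichotomy
  and non-negativity; assignment coverage sweeps use 100 seeded scenes
  of 8 objects on a 128×128 image with a 3-size × 3-ratio anchor grid —
  sizes chosen so the full suite exercises every branch and metric in
  seconds while keeping anchor counts (576) representative of a real
  grid's density per cell.
* CSV output uses full 17-digit precision so write→read→write round
  trips are byte-identical; the CLI's result tables use 6 significant
  digits for readable diffs.

## Known limitations

* TSD ignores box size entirely, so it cannot by itself distinguish a
  well-sized detection from a badly-sized one at the same center; the
  loss's contain branch reintroduces size via the radius mismatch, but
  assignment and NMS under pure TSD trade overlap awareness for center
  awareness. Coarser NMS behavior (suppressing genuinely distinct
  overlapping neighbors that happen to be close in center distance) is
  the known cost in dense scenes.
* The default TSD thresholds for assignment and NMS are conventions
  carried over from IoU, not tuned values.
* Only axis-aligned 2-D boxes are supported; no rotated or polygonal
  geometry.
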