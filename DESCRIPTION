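Package: tsdbox
Title: Truncated Structurally Aware Distance for Small-Object Bounding Boxes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Similarity metrics and regression losses for axis-aligned
    bounding boxes in dense small-object detection, centered on the
    truncated structurally aware distance (TSD): a scale-insensitive
    similarity built from the Chebyshev distance between box centers,
    standardized by the dataset's mean ground-truth area. Includes the
    IoU, GIoU, DIoU and CIoU baselines, a branch-structured TSD
    regression loss with closed-form gradients, metric-pluggable anchor
    label assignment and non-maximum suppression, a synthetic
    dense-small-object scene generator, deviation-curve and
    relationship-sweep analyses, and readers/writers for COCO-style and
    CSV box annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
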