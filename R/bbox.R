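#' Axis-aligned bounding box
#'
#' A box is stored as upper-left corner plus extent, `(x, y, w, h)`, in pixel
#' units with a 0-based coordinate system: the box covers the half-open pixel
#' range `[x, x + w) x [y, y + h)`, so its area is `w * h` and its centroid is
#' `(x + w/2, y + h/2)`. Coordinates may be real-valued; rasterization (for
#' mask rendering and the pixel-painting oracle) rounds to pixel centres.
#'
#' @param x,y Upper-left corner (column, row), 0-based pixels.
#' @param w,h Width and height in pixels; must be strictly positive.
#' @return An object of class `bbox`: a named numeric vector `(x, y, w, h)`.
#' @examples
#' b <- bbox(10, 20, 30, 40)
#' bbox_centroid(b)
#' @export
bbox <- function(x, y, w, h) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(w), is.numeric(h))
  if (w <= 0 || h <= 0) stop("bbox width and height must be positive")
  structure(c(x = as.numeric(x), y = as.numeric(y),
              w = as.numeric(w), h = as.numeric(h)),
            class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox x=%g y=%g w=%g h=%g>\n", x["x"], x["y"], x["w"], x["h"]))
  invisible(x)
}

as_bbox <- function(b) {
  if (inherits(b, "bbox")) return(b)
  b <- as.numeric(b)
  if (length(b) != 4) stop("a bbox needs exactly 4 values (x, y, w, h)")
  bbox(b[1], b[2], b[3], b[4])
}

#' @rdname bbox
#' @param b A `bbox`.
#' @export
bbox_centroid <- function(b) {
  b <- as_bbox(b)
  c(x = unname(b["x"] + b["w"] / 2), y = unname(b["y"] + b["h"] / 2))
}

#' Check that a box lies inside an image
#'
#' @param b A `bbox`.
#' @param image_w,image_h Image width and height in pixels.
#' @return `TRUE` or `FALSE`.
#' @export
bbox_in_image <- function(b, image_w, image_h) {
  b <- as_bbox(b)
  b["x"] >= 0 && b["y"] >= 0 &&
    b["x"] + b["w"] <= image_w && b["y"] + b["h"] <= image_h
}

intersection_area <- function(a, b) {
  iw <- min(a["x"] + a["w"], b["x"] + b["w"]) - max(a["x"], b["x"])
  ih <- min(a["y"] + a["h"], b["y"] + b["h"]) - max(a["y"], b["y"])
  if (iw <= 0 || ih <= 0) return(0)
  unname(iw * ih)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes (`bbox` or length-4 numeric `(x, y, w, h)`).
#' @return IoU in `[0, 1]`; disjoint boxes give 0, identical boxes give 1.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10))  # 1/3
#' @export
iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  inter <- intersection_area(a, b)
  uni <- unname(a["w"] * a["h"] + b["w"] * b["h"]) - inter
  inter / uni
}

#' Area precision and recall of a predicted box against a reference box
#'
#' Precision is the fraction of the predicted box's area that overlaps the
#' reference; recall is the fraction of the reference covered by the
#' prediction. Both reduce to IoU-style area ratios on a single box pair,
#' which is how per-image precision/recall are reported alongside IoU here.
#'
#' @param pred Predicted box.
#' @param gt Reference (ground-truth) box.
#' @return Named numeric vector `c(precision =, recall =)`.
#' @export
area_precision_recall <- function(pred, gt) {
  pred <- as_bbox(pred); gt <- as_bbox(gt)
  inter <- intersection_area(pred, gt)
  c(precision = inter / unname(pred["w"] * pred["h"]),
    recall = inter / unname(gt["w"] * gt["h"]))
}

#' Relative centroid distance between two boxes
#'
#' The localization error used for single-object detection:
#' `0.5 * (|x_g - x_e| / W + |y_g - y_e| / H)` where `(x_g, y_g)` and
#' `(x_e, y_e)` are the centroids of the reference and estimated boxes and
#' `W`, `H` are the image width and height. Unitless; 0 for coincident
#' centroids and at most 1 for boxes inside the image.
#'
#' @param gt Reference box.
#' @param est Estimated box.
#' @param image_w,image_h Image width and height in pixels (positive).
#' @return Nonnegative scalar.
#' @export
centroid_distance <- function(gt, est, image_w, image_h) {
  if (image_w <= 0 || image_h <= 0) stop("image dimensions must be positive")
  cg <- bbox_centroid(gt)
  ce <- bbox_centroid(est)
  0.5 * (abs(cg["x"] - ce["x"]) / image_w + abs(cg["y"] - ce["y"]) / image_h)[[1]]
}

#' Per-image detection evaluation
#'
#' @param pred Predicted box.
#' @param gt Reference box.
#' @param image_w,image_h Image size in pixels.
#' @return One-row data frame with `iou`, `area_precision`, `area_recall`,
#'   `centroid_distance`.
#' @export
detection_eval <- function(pred, gt, image_w, image_h) {
  pr <- area_precision_recall(pred, gt)
  data.frame(iou = iou(pred, gt),
             area_precision = unname(pr["precision"]),
             area_recall = unname(pr["recall"]),
             centroid_distance = centroid_distance(gt, pred, image_w, image_h))
}

#' Success curve over a threshold sweep
#'
#' For IoU, an image counts as a success when its IoU strictly exceeds the
#' threshold; for centroid distance, when the distance is strictly below it.
#' Default grids: IoU thresholds 0.0-0.9 in steps of 0.1, centroid distance
#' 0.01-0.1 in steps of 0.01.
#'
#' @param evals Data frame of per-image evaluations (from [detection_eval()]
#'   or [compare_annotations()]), or a numeric vector of metric values.
#' @param metric `"iou"` or `"centroid_distance"`.
#' @param thresholds Threshold grid; defaults depend on `metric`.
#' @return Data frame of class `success_curve` with columns `metric`,
#'   `threshold`, `rate`.
#' @export
success_curve <- function(evals, metric = c("iou", "centroid_distance"),
                          thresholds = NULL) {
  metric <- match.arg(metric)
  vals <- if (is.data.frame(evals)) evals[[metric]] else as.numeric(evals)
  if (length(vals) == 0) stop("no evaluations supplied")
  if (is.null(thresholds)) {
    thresholds <- if (metric == "iou") seq(0, 0.9, by = 0.1)
                  else seq(0.01, 0.1, by = 0.01)
  }
  if (length(thresholds) == 0) stop("empty threshold grid")
  rate <- vapply(thresholds, function(t) {
    if (metric == "iou") mean(vals > t) else mean(vals < t)
  }, numeric(1))
  structure(data.frame(metric = metric, threshold = thresholds, rate = rate),
            class = c("success_curve", "data.frame"))
}

#' Success rate at a single threshold
#'
#' @inheritParams success_curve
#' @param threshold Single threshold value.
#' @return Fraction of images counted as successes.
#' @export
success_rate <- function(evals, metric = c("iou", "centroid_distance"),
                         threshold) {
  success_curve(evals, metric, thresholds = threshold)$rate
}

# population standard deviation, matching mean +/- sd aggregation across
# folds/images where the folds are the whole population of interest
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Compare two aligned annotation sets
#'
#' Treats `set_a` as the reference and `set_b` as the estimate, evaluating
#' every index-aligned pair. Swapping the roles of the two sets swaps area
#' precision and recall and leaves IoU and centroid distance unchanged.
#'
#' @param set_a Reference boxes: list of `bbox` (or 4-vectors).
#' @param set_b Estimated boxes, same length and order.
#' @param image_sizes Either a single `c(w, h)` applied to all images or a
#'   list of per-image `c(w, h)`.
#' @return List with `per_image` (data frame of per-image metrics), `mean`
#'   and `sd` (named vectors over the four metrics; population sd).
#' @export
compare_annotations <- function(set_a, set_b, image_sizes) {
  if (length(set_a) != length(set_b))
    stop("annotation sets must be index-aligned and of equal length")
  n <- length(set_a)
  if (n == 0) stop("empty annotation sets")
  if (!is.list(image_sizes)) image_sizes <- rep(list(image_sizes), n)
  if (length(image_sizes) != n) stop("need one image size per annotation")
  per <- do.call(rbind, lapply(seq_len(n), function(i) {
    sz <- image_sizes[[i]]
    detection_eval(pred = set_b[[i]], gt = set_a[[i]],
                   image_w = sz[1], image_h = sz[2])
  }))
  list(per_image = per,
       mean = vapply(per, mean, numeric(1)),
       sd = vapply(per, sd_pop, numeric(1)))
}
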