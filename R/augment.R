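# Geometric augmentation applied identically to an image and its label
# (box or mask). Transforms are affine maps about the image centre in
# continuous pixel coordinates (x = column + 0.5, y = row + 0.5, 0-based).

affine_about_center <- function(A, w, h) {
  cx <- w / 2; cy <- h / 2
  shift <- c(cx, cy) - A %*% c(cx, cy)
  cbind(A, shift)
}

compose2x3 <- function(m2, m1) {  # apply m1 then m2
  A <- m2[, 1:2] %*% m1[, 1:2]
  t <- m2[, 1:2] %*% m1[, 3] + m2[, 3]
  cbind(A, t)
}

apply2x3 <- function(m, pts) {  # pts: 2 x n
  m[, 1:2] %*% pts + m[, 3]
}

invert2x3 <- function(m) {
  Ai <- solve(m[, 1:2])
  cbind(Ai, -Ai %*% m[, 3])
}

# sample a random forward transform from the configured op set
sample_affine <- function(ops, w, h,
                          rotate_deg = 15, shear_deg = 10, flip_p = 0.5) {
  A <- diag(2)
  if ("hflip" %in% ops && stats::runif(1) < flip_p)
    A <- diag(c(-1, 1)) %*% A
  if ("vflip" %in% ops && stats::runif(1) < flip_p)
    A <- diag(c(1, -1)) %*% A
  if ("shear" %in% ops) {
    s <- tan(stats::runif(1, -shear_deg, shear_deg) * pi / 180)
    A <- matrix(c(1, 0, s, 1), 2, 2) %*% A
  }
  if ("rotate" %in% ops) {
    th <- stats::runif(1, -rotate_deg, rotate_deg) * pi / 180
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*% A
  }
  affine_about_center(A, w, h)
}

transform_bbox <- function(box, m, w, h) {
  box <- as_bbox(box)
  corners <- rbind(
    c(box[["x"]], box[["x"]] + box[["w"]], box[["x"]], box[["x"]] + box[["w"]]),
    c(box[["y"]], box[["y"]], box[["y"]] + box[["h"]], box[["y"]] + box[["h"]]))
  tc <- apply2x3(m, corners)
  x0 <- max(0, min(tc[1, ])); x1 <- min(w, max(tc[1, ]))
  y0 <- max(0, min(tc[2, ])); y1 <- min(h, max(tc[2, ]))
  if (x1 - x0 <= 0 || y1 - y0 <= 0) {
    stop(structure(class = c("degenerate_augmentation", "error", "condition"),
                   list(message = "transform pushed the box outside the image",
                        call = sys.call(-1))))
  }
  bbox(x0, y0, x1 - x0, y1 - y0)
}

#' Apply one random geometric augmentation to an image and its label
#'
#' Draws a random transform from the configured operation set (flips with
#' probability `flip_p`, rotation and shear angles uniform in their ranges)
#' and applies the identical transform to the image and to its label. A box
#' label becomes the tight axis-aligned box of its transformed corners,
#' clipped to the image; a mask label is warped with the same bilinear map
#' as the image. If the transform pushes the whole box outside the image a
#' `degenerate_augmentation` condition is signalled so the caller can
#' re-draw.
#'
#' @param image `H x W x C` (or `H x W`) numeric array.
#' @param label A `bbox` or a mask matrix aligned with `image`.
#' @param ops Character subset of `c("hflip", "vflip", "rotate", "shear")`.
#'   Empty set returns the inputs unchanged.
#' @param rotate_deg,shear_deg Half-ranges in degrees (rotation +/-15,
#'   shear +/-10 by default).
#' @param flip_p Per-axis flip probability.
#' @param fill Fill value for pixels mapped from outside the image.
#' @return `list(image =, label =)` after the shared transform.
#' @export
augment_pair <- function(image, label, ops = c("hflip", "vflip", "rotate",
                                               "shear"),
                         rotate_deg = 15, shear_deg = 10, flip_p = 0.5,
                         fill = 0) {
  if (length(ops) == 0) return(list(image = image, label = label))
  ops <- match.arg(ops, c("hflip", "vflip", "rotate", "shear"),
                   several.ok = TRUE)
  d <- dim(image)
  was2d <- length(d) == 2
  if (was2d) dim(image) <- c(d, 1)
  h <- dim(image)[1]; w <- dim(image)[2]
  m <- sample_affine(ops, w, h, rotate_deg, shear_deg, flip_p)
  label_out <- if (is.null(label)) {
    NULL
  } else if (inherits(label, "bbox") ||
                   (is.numeric(label) && length(label) == 4 && is.null(dim(label)))) {
    transform_bbox(label, m, w, h)  # may signal degenerate_augmentation
  } else {
    lab <- unclass(label)
    ld <- dim(lab)
    l2d <- length(ld) == 2
    if (l2d) dim(lab) <- c(ld, 1)
    out <- nn_warp_affine(lab, invert2x3(m), fill,
                          as.integer(dim(lab)[1]), as.integer(dim(lab)[2]))
    if (l2d) dim(out) <- ld
    out
  }
  img_out <- nn_warp_affine(image, invert2x3(m), fill,
                            as.integer(h), as.integer(w))
  if (was2d) dim(img_out) <- d
  list(image = img_out, label = label_out)
}

# augment with bounded re-draws on degenerate box transforms
augment_pair_retry <- function(image, box, ops, rotate_deg, shear_deg,
                               flip_p, max_tries = 10) {
  for (i in seq_len(max_tries)) {
    res <- tryCatch(
      augment_pair(image, box, ops, rotate_deg, shear_deg, flip_p),
      degenerate_augmentation = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  list(image = image, label = box)  # give up: keep the original pair
}
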