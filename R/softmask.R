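#' Render a bounding box as a bivariate-Gaussian soft mask
#'
#' Instead of a hard 0/1 mask, a box annotation is encoded as a bell-shaped
#' per-pixel probability map: an axis-aligned bivariate Gaussian centred on
#' the box centroid with peak value 1 and zero covariance between axes. The
#' value at pixel `(i, j)` (0-based, centre at `(j + 0.5, i + 0.5)`) is
#' `exp(-0.5 * (((j + 0.5 - mx) / sx)^2 + ((i + 0.5 - my) / sy)^2))`.
#'
#' The spread is tied to the box extent via `sigma_mode`:
#' * `std_half_extent` (default): `sx = w/2`, `sy = h/2` — the standard
#'   deviation equals the half-extent, so the 0.6 level set falls almost
#'   exactly on the box edge (`sqrt(-2 log 0.6) ~ 1.011` half-extents).
#' * `var_half_extent`: `sx^2 = w/2`, `sy^2 = h/2` — a literal
#'   variance-equals-half-extent reading, offered for comparison.
#'
#' @param box A `bbox` inside the image.
#' @param image_h,image_w Mask size in pixels.
#' @param sigma_mode See Details.
#' @return `soft_mask`: an `image_h x image_w` numeric matrix in `[0, 1]`.
#' @examples
#' m <- render_soft_mask(bbox(40, 40, 40, 40), 128, 128)
#' max(m)  # ~1 at the centroid pixel
#' @export
render_soft_mask <- function(box, image_h, image_w,
                             sigma_mode = c("std_half_extent",
                                            "var_half_extent")) {
  sigma_mode <- match.arg(sigma_mode)
  box <- as_bbox(box)
  if (!bbox_in_image(box, image_w, image_h))
    stop("box lies outside the image")
  mu <- bbox_centroid(box)
  if (sigma_mode == "std_half_extent") {
    sx <- box[["w"]] / 2
    sy <- box[["h"]] / 2
  } else {
    sx <- sqrt(box[["w"]] / 2)
    sy <- sqrt(box[["h"]] / 2)
  }
  gx <- exp(-0.5 * ((seq_len(image_w) - 0.5 - mu[["x"]]) / sx)^2)
  gy <- exp(-0.5 * ((seq_len(image_h) - 0.5 - mu[["y"]]) / sy)^2)
  structure(outer(gy, gx), class = c("soft_mask", "matrix"))
}

#' Peak-normalize a mask
#'
#' Rescales so the maximum value is exactly 1. Decoding is invariant to
#' positive rescaling of its input because of this step.
#'
#' @param mask Numeric matrix with at least one strictly positive value.
#' @return Matrix with `max == 1`.
#' @export
peak_normalize <- function(mask) {
  m <- max(mask)
  if (!is.finite(m) || m <= 0) stop("mask has no positive values to normalize")
  mask / m
}

#' Decode a soft mask into a bounding box
#'
#' The predicted mask is peak-normalized to 1, thresholded (strictly
#' greater-than), and only the connected component containing the global
#' peak is kept; the returned box is the tight axis-aligned bounding box of
#' that component. Ties for the global peak are broken by first occurrence
#' in row-major order. Secondary blobs elsewhere in the mask are ignored —
#' the decoder assumes a single object of interest.
#'
#' @param mask Numeric matrix (any positive scale; normalized internally).
#' @param threshold Probability threshold in (0, 1); default 0.6.
#' @param connectivity Pixel connectivity for the peak component, 4 or 8.
#' @return A `bbox` in the mask's pixel coordinates.
#' @export
decode_mask_to_bbox <- function(mask, threshold = 0.6, connectivity = 8) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  mask <- unclass(mask)
  if (!any(mask > 0)) stop("all-zero mask: no detection")
  mask <- peak_normalize(mask)
  H <- nrow(mask); W <- ncol(mask)
  peaks <- which(mask == max(mask), arr.ind = TRUE)
  # row-major first occurrence among ties
  ord <- order((peaks[, 1] - 1) * W + (peaks[, 2] - 1))
  pi <- peaks[ord[1], 1]; pj <- peaks[ord[1], 2]
  keep <- mask > threshold
  keep[pi, pj] <- TRUE  # the peak itself (value 1) always belongs to the box
  bb <- nn_peak_component_box(keep, pi, pj, as.integer(connectivity))
  bbox(x = bb[3] - 1, y = bb[1] - 1,
       w = bb[4] - bb[3] + 1, h = bb[2] - bb[1] + 1)
}

#' Binary cross-entropy between two masks
#'
#' Mean over pixels of `-(t log p + (1 - t) log(1 - p))`, with predictions
#' clipped to `[eps, 1 - eps]` for numerical safety.
#'
#' @param pred,target Numeric matrices/arrays of identical shape, values in
#'   `[0, 1]`.
#' @param eps Clipping constant (default `1e-7`).
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ")
  p <- pmin(pmax(pred, eps), 1 - eps)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

#' Persist a soft mask
#'
#' PNG output stores `round(255 * p)` as 8-bit grayscale (convenient to view,
#' quantized); RDS output is lossless and is the authoritative format for
#' round trips.
#'
#' @param mask A soft mask matrix.
#' @param path Output path ending in `.png` or `.rds`.
#' @export
write_mask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(round(255 * unclass(mask)) / 255, path)
  } else if (ext == "rds") {
    saveRDS(unclass(mask), path)
  } else stop("unsupported mask format: ", ext)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a[, , 1] else a
  } else if (ext == "rds") {
    readRDS(path)
  } else stop("unsupported mask format: ", ext)
  structure(m, class = c("soft_mask", "matrix"))
}
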