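#' Synthetic endoscopy-like image generator configuration
#'
#' The generator emulates the one salient structure the detector is trained
#' on: a single bright ellipse-like "ampulla" blob with radial falloff and
#' multiplicative texture, sitting on a cluttered darker background with
#' dimmer distractor blobs, a smooth illumination gradient and pixel noise.
#' Difficulty labels derive from latent visual features (blob size, clutter,
#' contrast, a dark crease band across the blob) so difficulty classifiers
#' have something learnable; `difficulty_feature_strength` < 1 injects
#' label noise by re-drawing the visual features from a random class.
#'
#' Class mix default `(0.68, 0.13, 0.18, 0.01)` follows a realistic
#' clinical distribution of cannulation outcomes (roughly two-thirds easy,
#' failure rare at about 1%).
#'
#' @param n_images Number of images.
#' @param image_size Square image side in pixels.
#' @param blob_scale_range Target blob diameter as a fraction of the image
#'   side.
#' @param aspect_range Width/height aspect ratio range of the blob.
#' @param texture_noise_sd Additive pixel noise, in 8-bit gray levels.
#' @param n_distractors Baseline count of background clutter blobs (class
#'   latents scale it).
#' @param difficulty_feature_strength In `[0, 1]`: probability that an
#'   image's visual features match its difficulty class.
#' @param class_mix Proportions over
#'   `(easy, over_5min, additional_technique, failure)`; must sum to 1.
#' @param contrast_margin Minimum excess of mean blob-interior intensity
#'   over the background mean, in 8-bit gray levels.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_images = 200, image_size = 64,
                         blob_scale_range = c(0.1, 0.4),
                         aspect_range = c(0.5, 2),
                         texture_noise_sd = 8, n_distractors = 4,
                         difficulty_feature_strength = 1,
                         class_mix = c(easy = 0.68, over_5min = 0.13,
                                       additional_technique = 0.18,
                                       failure = 0.01),
                         contrast_margin = 40, seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (length(class_mix) != 4) stop("class_mix needs 4 proportions")
  names(class_mix) <- difficulty_levels()
  stopifnot(difficulty_feature_strength >= 0,
            difficulty_feature_strength <= 1)
  structure(list(n_images = n_images, image_size = image_size,
                 blob_scale_range = blob_scale_range,
                 aspect_range = aspect_range,
                 texture_noise_sd = texture_noise_sd,
                 n_distractors = n_distractors,
                 difficulty_feature_strength = difficulty_feature_strength,
                 class_mix = class_mix, contrast_margin = contrast_margin,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# class-conditional visual latents; the links (small blob + clutter =>
# slow cannulation, crease across the blob => additional techniques,
# minimal contrast + maximal clutter => failure) are synthetic constructions
# for testability, not claims about real anatomy
class_latents <- function(class, cfg) {
  lo <- cfg$blob_scale_range[1]; hi <- cfg$blob_scale_range[2]
  mid <- (lo + hi) / 2
  margin_c <- cfg$contrast_margin / 255
  switch(class,
    easy = list(scale = stats::runif(1, mid, hi),
                peak_contrast = stats::runif(1, 0.55, 0.65),
                n_distractors = cfg$n_distractors %/% 2,
                crease = FALSE),
    over_5min = list(scale = stats::runif(1, lo, lo + 0.25 * (hi - lo)),
                     peak_contrast = stats::runif(1, 0.42, 0.5),
                     n_distractors = 2 * cfg$n_distractors,
                     crease = FALSE),
    additional_technique = list(scale = stats::runif(1, mid * 0.9, hi * 0.9),
                                peak_contrast = stats::runif(1, 0.5, 0.6),
                                n_distractors = cfg$n_distractors,
                                crease = TRUE),
    failure = list(scale = stats::runif(1, lo, lo + 0.3 * (hi - lo)),
                   # minimal contrast: just above the learnability margin
                   peak_contrast = 2.6 * margin_c,
                   n_distractors = 3 * cfg$n_distractors,
                   crease = FALSE))
}

sample_outcome <- function(class) {
  switch(class,
    easy = list(cannulation_time_s = round(stats::runif(1, 30, 300), 3),
                additional_technique = FALSE, success = TRUE),
    over_5min = list(cannulation_time_s = round(stats::runif(1, 301, 1200), 3),
                     additional_technique = FALSE, success = TRUE),
    additional_technique = list(cannulation_time_s =
                                  round(stats::runif(1, 301, 1200), 3),
                                additional_technique = TRUE, success = TRUE),
    failure = list(cannulation_time_s = NA_real_,
                   additional_technique = FALSE, success = FALSE))
}

# additive ellipse blob with (1 - rho^2) falloff; returns the field only
ellipse_blob <- function(S, cx, cy, ax, ay, peak) {
  x <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE)
  y <- matrix(seq_len(S) - 0.5, S, S)
  rho2 <- ((x - cx) / ax)^2 + ((y - cy) / ay)^2
  peak * pmax(1 - rho2, 0)
}

generate_sample <- function(cfg, class) {
  S <- cfg$image_size
  visual_class <- class
  if (stats::runif(1) > cfg$difficulty_feature_strength)
    visual_class <- sample(difficulty_levels(), 1)
  lat <- class_latents(visual_class, cfg)

  # target geometry: semi-axes from scale and aspect, kept inside the frame
  r <- stats::runif(1, cfg$aspect_range[1], cfg$aspect_range[2])
  ax <- lat$scale * S / 2 * sqrt(r)
  ay <- lat$scale * S / 2 / sqrt(r)
  ax <- min(max(ax, 2), S / 2 - 1)
  ay <- min(max(ay, 2), S / 2 - 1)
  cx <- stats::runif(1, ax + 1, S - ax - 1)
  cy <- stats::runif(1, ay + 1, S - ay - 1)

  bg_level <- stats::runif(1, 0.25, 0.4)
  gdir <- stats::runif(1, 0, 2 * pi)
  gx <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE) / S - 0.5
  gy <- matrix(seq_len(S) - 0.5, S, S) / S - 0.5
  img <- bg_level + 0.08 * (cos(gdir) * gx + sin(gdir) * gy)

  for (d in seq_len(lat$n_distractors)) {
    dax <- stats::runif(1, 0.03, 0.08) * S
    day <- stats::runif(1, 0.03, 0.08) * S
    img <- img + ellipse_blob(S, stats::runif(1, 0, S), stats::runif(1, 0, S),
                              dax, day, stats::runif(1, 0.05, 0.12))
  }

  blob <- ellipse_blob(S, cx, cy, ax, ay, lat$peak_contrast)
  texture <- 1 + 0.1 * matrix(stats::rnorm(S * S), S, S)
  blob <- blob * texture
  if (lat$crease) {
    # dark band across the upper part of the blob
    yy <- matrix(seq_len(S) - 0.5, S, S)
    band <- abs(yy - (cy - 0.4 * ay)) < 0.18 * ay
    blob[band] <- blob[band] * 0.25
  }
  img <- img + blob + stats::rnorm(S * S, sd = cfg$texture_noise_sd / 255)
  img <- pmin(pmax(img, 0), 1)

  # endoscopy-like warm tint, quantized to the 8-bit grid so PNG round
  # trips are exact
  rgb <- array(0, c(S, S, 3))
  rgb[, , 1] <- img
  rgb[, , 2] <- img * 0.8
  rgb[, , 3] <- img * 0.62
  rgb <- round(rgb * 255) / 255

  gt_box <- bbox(round(cx - ax, 3), round(cy - ay, 3),
                 round(2 * ax, 3), round(2 * ay, 3))
  list(image = rgb, gt_box = gt_box, outcome = sample_outcome(class),
       latent = c(lat, list(class = class, visual_class = visual_class,
                            cx = cx, cy = cy, ax = ax, ay = ay)))
}

#' Generate a synthetic labelled dataset
#'
#' Each sample carries the image, the tight bounding box of the target
#' blob's support ellipse, a procedural outcome record consistent with the
#' sampled difficulty class, and the latent generator parameters. The same
#' configuration (including seed) reproduces the dataset exactly.
#'
#' @param config A [synth_config()].
#' @return List of samples `list(image, gt_box, outcome, latent)`.
#' @examples
#' ds <- generate_dataset(synth_config(n_images = 4, seed = 7))
#' ds[[1]]$gt_box
#' @export
generate_dataset <- function(config = synth_config()) {
  set.seed(config$seed)
  classes <- sample(difficulty_levels(), config$n_images, replace = TRUE,
                    prob = config$class_mix)
  lapply(classes, function(cl) generate_sample(config, cl))
}

#' Write a dataset to disk as a fixture directory
#'
#' Layout: `images/img_%04d.png` (8-bit RGB), `annotations.json` and
#' `annotations.csv` (both dialects of [write_annotations()]),
#' `outcomes.csv`. Reading the fixture back reproduces images, boxes and
#' outcomes exactly.
#'
#' @param dir Output directory (created if missing).
#' @param samples Dataset from [generate_dataset()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, samples) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  nms <- sprintf("img_%04d.png", seq_along(samples))
  boxes <- lapply(samples, `[[`, "gt_box")
  names(boxes) <- nms
  for (i in seq_along(samples))
    png::writePNG(samples[[i]]$image, file.path(dir, "images", nms[i]))
  write_annotations(boxes, file.path(dir, "annotations.json"))
  write_annotations(boxes, file.path(dir, "annotations.csv"))
  out <- data.frame(
    image = nms,
    cannulation_time_s = vapply(samples, function(s)
      s$outcome$cannulation_time_s, numeric(1)),
    additional_technique = vapply(samples, function(s)
      s$outcome$additional_technique, logical(1)),
    success = vapply(samples, function(s) s$outcome$success, logical(1)))
  write_outcomes(out, file.path(dir, "outcomes.csv"))
  invisible(dir)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir Directory written by [write_fixture()].
#' @return List of samples `list(image, gt_box, outcome)` in annotation
#'   order.
#' @export
read_fixture <- function(dir) {
  boxes <- read_annotations(file.path(dir, "annotations.json"))
  outcomes <- read_outcomes(file.path(dir, "outcomes.csv"))
  lapply(names(boxes), function(nm) {
    o <- outcomes[outcomes$image == nm, ]
    list(image = png::readPNG(file.path(dir, "images", nm)),
         gt_box = boxes[[nm]],
         outcome = list(cannulation_time_s = o$cannulation_time_s,
                        additional_technique = o$additional_technique,
                        success = o$success))
  })
}
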