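#' Detector configuration
#'
#' Hyper-parameters for the soft-mask detector and the bbox-regressor
#' baseline. Defaults target a compact from-scratch network that trains in
#' minutes on one CPU; they are deliberately small stand-ins for the large
#' pretrained encoders used in clinical-scale work, and every field can be
#' raised for bigger experiments.
#'
#' @param input_size Square input side in pixels; must be divisible by
#'   `2^depth`.
#' @param base_channels Channels of the first encoder stage; doubled at each
#'   downsampling.
#' @param depth Number of encoder (pool) stages.
#' @param learning_rate Adam step size.
#' @param max_epochs Upper bound on training epochs.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of the training set held out for validation
#'   and early stopping.
#' @param augmentation Character subset of
#'   `c("hflip", "vflip", "rotate", "shear")`; empty vector disables
#'   augmentation.
#' @param rotate_deg,shear_deg,flip_p Augmentation parameter ranges.
#' @param sigma_mode Soft-mask rendering mode, see [render_soft_mask()].
#' @param decode_threshold Mask-to-box decoding threshold.
#' @param seed Integer seed fixing initialization, shuffling and
#'   augmentation.
#' @return A `detector_config` list.
#' @export
detector_config <- function(input_size = 128, base_channels = 16, depth = 3,
                            learning_rate = 1e-3, max_epochs = 30,
                            early_stop_patience = 10, batch_size = 16,
                            val_fraction = 0.15,
                            augmentation = c("hflip", "vflip", "rotate",
                                             "shear"),
                            rotate_deg = 15, shear_deg = 10, flip_p = 0.5,
                            sigma_mode = "std_half_extent",
                            decode_threshold = 0.6, seed = 1L) {
  if (input_size %% 2^depth != 0)
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = input_size, base_channels = base_channels,
                 depth = depth, learning_rate = learning_rate,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 batch_size = batch_size, val_fraction = val_fraction,
                 augmentation = augmentation, rotate_deg = rotate_deg,
                 shear_deg = shear_deg, flip_p = flip_p,
                 sigma_mode = sigma_mode,
                 decode_threshold = decode_threshold, seed = as.integer(seed)),
            class = "detector_config")
}

# scale a dataset sample to the network input size; returns image + box
prepare_sample <- function(sample, input_size) {
  img <- sample$image
  h <- dim(img)[1]; w <- dim(img)[2]
  box <- as_bbox(sample$gt_box)
  if (h != input_size || w != input_size) {
    img <- resize_image(img, input_size, input_size)
    sx <- input_size / w; sy <- input_size / h
    box <- bbox(box[["x"]] * sx, box[["y"]] * sy,
                box[["w"]] * sx, box[["h"]] * sy)
  }
  list(image = img, box = box)
}

split_train_val <- function(n, val_fraction) {
  n_val <- max(1, round(n * val_fraction))
  idx <- sample.int(n)
  list(val = idx[seq_len(n_val)], train = idx[-seq_len(n_val)])
}

# success@IoU 0.3 and validation loss (BCE or MAE) on a prepared sample list
detector_val_metrics <- function(type, params, config, samples) {
  S <- config$input_size
  res <- vapply(samples, function(s) {
    x <- stack_images(list(s$image))
    if (type == "soft_mask") {
      fw <- unet_fw(params, x, config$depth)
      mask <- sigmoid(fw$logit[, , 1, 1])
      tgt <- unclass(render_soft_mask(s$box, S, S, config$sigma_mode))
      pred <- decode_mask_to_bbox(mask, threshold = config$decode_threshold)
      c(iou(pred, s$box), bce_loss(mask, tgt))
    } else {
      fw <- encoder_fw(params, x, config$depth)
      v <- sigmoid(fw$scores[, 1])
      b <- s$box
      tgt <- c(b[["x"]], b[["y"]], b[["w"]], b[["h"]]) / S
      pred <- regressor_to_bbox(v, S)
      c(iou(pred, s$box), mean(abs(v - tgt)))
    }
  }, numeric(2))
  c(success = mean(res[1, ] > 0.3), loss = mean(res[2, ]))
}

detector_forward_one <- function(type, params, config, img) {
  x <- stack_images(list(img))
  if (type == "soft_mask") {
    fw <- unet_fw(params, x, config$depth)
    mask <- sigmoid(fw$logit[, , 1, 1])
    decode_mask_to_bbox(mask, threshold = config$decode_threshold)
  } else {
    fw <- encoder_fw(params, x, config$depth)
    regressor_to_bbox(sigmoid(fw$scores[, 1]), config$input_size)
  }
}

# normalized (x, y, w, h) in [0, 1] -> pixel bbox, clamped valid
regressor_to_bbox <- function(v, size) {
  w <- max(1, v[3] * size)
  h <- max(1, v[4] * size)
  x <- min(max(v[1] * size, 0), size - w)
  y <- min(max(v[2] * size, 0), size - h)
  bbox(max(x, 0), max(y, 0), min(w, size), min(h, size))
}

#' Train the soft-mask ampulla detector
#'
#' Boxes are rendered as bivariate-Gaussian soft masks and a small U-Net
#' style encoder-decoder is fitted with binary cross-entropy. An internal
#' validation split drives early stopping on the validation success rate at
#' IoU 0.3 (fraction of validation images whose decoded box overlaps the
#' reference with IoU > 0.3); the returned weights are those of the best
#' validation epoch.
#'
#' @param dataset List of samples, each `list(image = H x W x 3 array in
#'   [0, 1], gt_box = bbox)` (as produced by [generate_dataset()] or
#'   [read_fixture()]).
#' @param config A [detector_config()].
#' @return A `trained_detector` with elements `params`, `config`, `log`
#'   (one row per epoch: train loss, validation success rate), `best_epoch`,
#'   `type = "soft_mask"`.
#' @export
train_soft_mask_detector <- function(dataset, config = detector_config()) {
  train_detector_impl(dataset, config, type = "soft_mask")
}

#' Train the direct bbox-regression baseline
#'
#' Same encoder as the soft-mask model, but the head global-average-pools
#' the deepest features and regresses `(x, y, w, h)` normalized to `[0, 1]`,
#' trained with mean absolute error. Evaluation is identical to the
#' soft-mask path, which makes the two models directly comparable on
#' success plots.
#'
#' @inheritParams train_soft_mask_detector
#' @return A `trained_detector` with `type = "bbox"`.
#' @export
train_bbox_regressor <- function(dataset, config = detector_config()) {
  train_detector_impl(dataset, config, type = "bbox")
}

train_detector_impl <- function(dataset, config, type) {
  if (length(dataset) == 0) stop("empty dataset")
  set.seed(config$seed)
  samples <- lapply(dataset, prepare_sample, input_size = config$input_size)
  sp <- split_train_val(length(samples), config$val_fraction)
  tr <- samples[sp$train]
  va <- samples[sp$val]
  if (length(tr) == 0) stop("no training samples after validation split")
  S <- config$input_size

  params <- if (type == "soft_mask") {
    unet_init(3, config$base_channels, config$depth)
  } else {
    encoder_init(3, config$base_channels, config$depth, 4)
  }
  opt <- adam_init(params)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_success_iou03 = numeric())
  best <- list(metric = -Inf, params = params, epoch = 0)
  stall <- 0

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(tr))
    losses <- numeric()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1, length(ord))]
      imgs <- vector("list", length(ids))
      boxes <- vector("list", length(ids))
      for (k in seq_along(ids)) {
        s <- tr[[ids[k]]]
        if (length(config$augmentation) > 0) {
          ap <- augment_pair_retry(s$image, s$box, config$augmentation,
                                   config$rotate_deg, config$shear_deg,
                                   config$flip_p)
          imgs[[k]] <- ap$image; boxes[[k]] <- ap$label
        } else {
          imgs[[k]] <- s$image; boxes[[k]] <- s$box
        }
      }
      x <- stack_images(imgs)
      if (type == "soft_mask") {
        tgt <- stack_images(lapply(boxes, function(b)
          unclass(render_soft_mask(b, S, S, config$sigma_mode))))
        fw <- unet_fw(params, x, config$depth)
        pr <- sigmoid(fw$logit)
        losses <- c(losses, bce_loss(pr, tgt))
        glogit <- (pr - tgt) / length(pr)
        grads <- unet_bw(params, fw$cache, glogit, config$depth)
      } else {
        tgt <- vapply(boxes, function(b) {
          b <- as_bbox(b)
          c(b[["x"]], b[["y"]], b[["w"]], b[["h"]]) / S
        }, numeric(4))
        fw <- encoder_fw(params, x, config$depth)
        pr <- sigmoid(fw$scores)
        losses <- c(losses, mean(abs(pr - tgt)))
        gscores <- sign(pr - tgt) * pr * (1 - pr) / length(pr)
        grads <- encoder_bw(params, fw$cache, gscores, config$depth)
      }
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
    }
    vms <- detector_val_metrics(type, params, config, va)
    vm <- vms[["success"]]
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(losses),
                                 val_loss = vms[["loss"]],
                                 val_success_iou03 = vm))
    if (vm > best$metric) {
      best <- list(metric = vm, params = params, epoch = epoch)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= config$early_stop_patience) break
    }
  }
  structure(list(params = best$params, config = config, log = log,
                 best_epoch = best$epoch, type = type),
            class = "trained_detector")
}

#' @export
print.trained_detector <- function(x, ...) {
  cat(sprintf(
    "<trained_detector type=%s epochs=%d best_epoch=%d val_success@IoU0.3=%.3f>\n",
    x$type, nrow(x$log), x$best_epoch, max(x$log$val_success_iou03)))
  invisible(x)
}

#' Predict the ampulla box for one image
#'
#' Runs the detector and, for the soft-mask model, decodes the predicted
#' mask with the configured peak-threshold rule. Boxes are mapped back to
#' the original image coordinates when the input had to be resized.
#'
#' @param model A `trained_detector`.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @return `list(mask =, box =)`; `mask` is `NULL` for the bbox-regressor
#'   (it predicts coordinates directly) and otherwise an `H x W` matrix in
#'   the original image size.
#' @export
predict_box <- function(model, image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  S <- model$config$input_size
  img <- if (h != S || w != S) resize_image(image, S, S) else image
  x <- stack_images(list(img))
  if (model$type == "soft_mask") {
    fw <- unet_fw(model$params, x, model$config$depth)
    mask <- sigmoid(fw$logit[, , 1, 1])
    box <- decode_mask_to_bbox(mask, threshold = model$config$decode_threshold)
    if (h != S || w != S) {
      box <- bbox(box[["x"]] * w / S, box[["y"]] * h / S,
                  box[["w"]] * w / S, box[["h"]] * h / S)
      mask <- resize_image(mask, h, w)
    }
    list(mask = structure(mask, class = c("soft_mask", "matrix")), box = box)
  } else {
    fw <- encoder_fw(model$params, x, model$config$depth)
    box <- regressor_to_bbox(sigmoid(fw$scores[, 1]), S)
    if (h != S || w != S)
      box <- bbox(box[["x"]] * w / S, box[["y"]] * h / S,
                  box[["w"]] * w / S, box[["h"]] * h / S)
    list(mask = NULL, box = box)
  }
}

#' Evaluate a detector on a labelled dataset
#'
#' @param model A `trained_detector`.
#' @param dataset List of samples with `image` and `gt_box`.
#' @return Data frame of per-image `iou`, `area_precision`, `area_recall`,
#'   `centroid_distance`.
#' @export
evaluate_detector <- function(model, dataset) {
  do.call(rbind, lapply(dataset, function(s) {
    pred <- predict_box(model, s$image)
    detection_eval(pred$box, as_bbox(s$gt_box),
                   image_w = dim(s$image)[2], image_h = dim(s$image)[1])
  }))
}

#' Save or load a trained model checkpoint
#'
#' Checkpoints bundle weights, configuration and the training log in one
#' RDS archive.
#'
#' @param model A `trained_detector` or `trained_classifier`.
#' @param path `.rds` path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
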