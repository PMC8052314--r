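#' Difficulty class levels
#'
#' Four-class scheme: `easy` (successful cannulation within 5 minutes, no
#' extra manoeuvres), `over_5min` (successful but slower than 5 minutes),
#' `additional_technique` (double-guidewire, needle-knife fistulotomy or a
#' device change was needed), `failure` (selective cannulation failed).
#' The binary scheme collapses everything but `easy` into `difficult`.
#'
#' @export
difficulty_levels <- function() {
  c("easy", "over_5min", "additional_technique", "failure")
}

#' Map a procedural outcome to difficulty labels
#'
#' Precedence: failure > additional technique > over 5 minutes > easy.
#' "Over 5 minutes" is strict (`time > 300` seconds). A failed cannulation
#' maps to `failure` regardless of the recorded time; the binary label is
#' `difficult` exactly when the four-class label is not `easy`.
#'
#' @param cannulation_time_s Cannulation time in seconds; may be `NA` when
#'   `success` is `FALSE`.
#' @param additional_technique Logical: were additional cannulation
#'   techniques used?
#' @param success Logical: did selective cannulation succeed?
#' @return `list(four_class =, binary =)` with factor levels
#'   [difficulty_levels()] and `c("easy", "difficult")`.
#' @examples
#' map_outcome(130, FALSE, TRUE)   # easy
#' map_outcome(301, FALSE, TRUE)   # over_5min
#' map_outcome(400, TRUE,  TRUE)   # additional_technique
#' @export
map_outcome <- function(cannulation_time_s, additional_technique, success) {
  if (!is.na(cannulation_time_s) && cannulation_time_s < 0)
    stop("cannulation time cannot be negative")
  four <- if (!success) {
    "failure"
  } else if (isTRUE(additional_technique)) {
    "additional_technique"
  } else {
    if (is.na(cannulation_time_s))
      stop("a successful cannulation needs a recorded time")
    if (cannulation_time_s > 300) "over_5min" else "easy"
  }
  list(four_class = factor(four, levels = difficulty_levels()),
       binary = factor(if (four == "easy") "easy" else "difficult",
                       levels = c("easy", "difficult")))
}

#' Map an outcomes data frame to difficulty labels
#'
#' @param outcomes Data frame with columns `cannulation_time_s`,
#'   `additional_technique`, `success` (as from [read_outcomes()]).
#' @return The input with `four_class` and `binary` factor columns added.
#' @export
map_outcomes <- function(outcomes) {
  labs <- lapply(seq_len(nrow(outcomes)), function(i)
    map_outcome(outcomes$cannulation_time_s[i],
                outcomes$additional_technique[i],
                outcomes$success[i]))
  outcomes$four_class <- factor(vapply(labs, function(l)
    as.character(l$four_class), character(1)), levels = difficulty_levels())
  outcomes$binary <- factor(vapply(labs, function(l)
    as.character(l$binary), character(1)), levels = c("easy", "difficult"))
  outcomes
}

#' Classifier configuration
#'
#' @inheritParams detector_config
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(input_size = 64, base_channels = 8, depth = 3,
                              learning_rate = 3e-3, max_epochs = 45,
                              early_stop_patience = 15, batch_size = 16,
                              val_fraction = 0.2,
                              augmentation = c("hflip", "vflip", "rotate",
                                               "shear"),
                              rotate_deg = 15, shear_deg = 10, flip_p = 0.5,
                              seed = 1L) {
  if (input_size %% 2^depth != 0)
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = input_size, base_channels = base_channels,
                 depth = depth, learning_rate = learning_rate,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 batch_size = batch_size, val_fraction = val_fraction,
                 augmentation = augmentation, rotate_deg = rotate_deg,
                 shear_deg = shear_deg, flip_p = flip_p,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

dataset_labels <- function(dataset, task) {
  vapply(dataset, function(s) {
    lab <- map_outcome(s$outcome$cannulation_time_s,
                       s$outcome$additional_technique,
                       s$outcome$success)
    as.character(if (task == "binary") lab$binary else lab$four_class)
  }, character(1))
}

task_levels <- function(task) {
  if (task == "binary") c("easy", "difficult") else difficulty_levels()
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Train a cannulation-difficulty classifier
#'
#' A compact CNN (shared encoder + global average pooling + linear head)
#' trained with cross-entropy on difficulty labels derived from procedural
#' outcomes. Per-iteration augmentation (flips, shears, rotations) and
#' early stopping on a validation metric guard against overfitting; the
#' stopping metric is selectable, mirroring the practice of keeping either
#' the best-accuracy or best-macro-F1 epoch.
#'
#' @param dataset List of samples `list(image, outcome)` where `outcome`
#'   has `cannulation_time_s`, `additional_technique`, `success` (as from
#'   [generate_dataset()] or [read_fixture()]).
#' @param task `"binary"` or `"four_class"`.
#' @param stop_metric `"macro_f1"` or `"accuracy"`: validation metric whose
#'   best epoch is kept.
#' @param config A [classifier_config()].
#' @return A `trained_classifier` with `params`, `config`, `log`,
#'   `best_epoch`, `task`, `levels`.
#' @export
train_difficulty_classifier <- function(dataset,
                                        task = c("binary", "four_class"),
                                        stop_metric = c("macro_f1",
                                                        "accuracy"),
                                        config = classifier_config()) {
  task <- match.arg(task)
  stop_metric <- match.arg(stop_metric)
  if (length(dataset) == 0) stop("empty dataset")
  set.seed(config$seed)
  levels <- task_levels(task)
  labels <- dataset_labels(dataset, task)

  # stratified validation split so rare classes appear on both sides
  folds <- stratified_folds(labels, k = max(2, round(1 / config$val_fraction)),
                            shuffle = TRUE)
  va_idx <- which(folds == 1)
  tr_idx <- which(folds != 1)
  tr_present <- table(factor(labels[tr_idx], levels = levels))
  if (any(tr_present < 2))
    stop("each class needs at least 2 training samples; missing: ",
         paste(names(tr_present)[tr_present < 2], collapse = ", "))

  S <- config$input_size
  prep <- function(img) {
    if (dim(img)[1] != S || dim(img)[2] != S) resize_image(img, S, S) else img
  }
  tr_imgs <- lapply(dataset[tr_idx], function(s) prep(s$image))
  va_imgs <- lapply(dataset[va_idx], function(s) prep(s$image))
  tr_y <- factor(labels[tr_idx], levels = levels)
  va_y <- factor(labels[va_idx], levels = levels)

  params <- encoder_init(3, config$base_channels, config$depth,
                         length(levels))
  opt <- adam_init(params)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_metric = numeric())
  best <- list(metric = -Inf, params = params, epoch = 0)
  stall <- 0

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(tr_imgs))
    losses <- numeric()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1, length(ord))]
      imgs <- lapply(tr_imgs[ids], function(img) {
        if (length(config$augmentation) > 0) {
          augment_pair(img, NULL, config$augmentation,
                       config$rotate_deg, config$shear_deg,
                       config$flip_p)$image
        } else img
      })
      x <- stack_images(imgs)
      y <- as.integer(tr_y[ids])
      fw <- encoder_fw(params, x, config$depth)
      p <- softmax_cols(fw$scores)
      onehot <- matrix(0, length(levels), length(ids))
      onehot[cbind(y, seq_along(ids))] <- 1
      losses <- c(losses, -mean(log(pmax(p[cbind(y, seq_along(ids))], 1e-12))))
      gscores <- (p - onehot) / length(ids)
      grads <- encoder_bw(params, fw$cache, gscores, config$depth)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
    }
    pred <- classifier_predict_labels(params, config, va_imgs, levels)
    cm <- confusion_matrix(va_y, pred$labels, levels)
    vm <- if (stop_metric == "accuracy") accuracy_from_cm(cm)
          else mean(f1_from_cm(cm))
    log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(losses),
                                 val_metric = vm))
    if (vm > best$metric) {
      best <- list(metric = vm, params = params, epoch = epoch)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= config$early_stop_patience) break
    }
  }
  structure(list(params = best$params, config = config, log = log,
                 best_epoch = best$epoch, task = task, levels = levels,
                 stop_metric = stop_metric),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf(
    "<trained_classifier task=%s stop=%s epochs=%d best=%d val=%.3f>\n",
    x$task, x$stop_metric, nrow(x$log), x$best_epoch, max(x$log$val_metric)))
  invisible(x)
}

classifier_predict_labels <- function(params, config, imgs, levels,
                                      batch = 32) {
  probs <- matrix(0, length(levels), length(imgs))
  for (start in seq(1, length(imgs), by = batch)) {
    ids <- start:min(start + batch - 1, length(imgs))
    x <- stack_images(imgs[ids])
    fw <- encoder_fw(params, x, config$depth)
    probs[, ids] <- softmax_cols(fw$scores)
  }
  list(probs = probs,
       labels = factor(levels[max.col(t(probs), ties.method = "first")],
                       levels = levels))
}

#' Predict difficulty labels and class probabilities
#'
#' @param model A `trained_classifier`.
#' @param dataset List of samples with `image`.
#' @return `list(labels = factor, probs = K x N matrix)` with rows in
#'   `model$levels` order.
#' @export
predict_difficulty <- function(model, dataset) {
  S <- model$config$input_size
  imgs <- lapply(dataset, function(s) {
    img <- s$image
    if (dim(img)[1] != S || dim(img)[2] != S) resize_image(img, S, S) else img
  })
  classifier_predict_labels(model$params, model$config, imgs, model$levels)
}

# ---- metrics ----------------------------------------------------------

confusion_matrix <- function(truth, pred, levels) {
  table(truth = factor(truth, levels = levels),
        pred = factor(pred, levels = levels))
}

precision_from_cm <- function(cm) {
  p <- diag(cm) / colSums(cm)
  p[is.nan(p)] <- 0
  p
}

recall_from_cm <- function(cm) {
  r <- diag(cm) / rowSums(cm)
  r[is.nan(r)] <- 0
  r
}

f1_from_cm <- function(cm) {
  p <- precision_from_cm(cm)
  r <- recall_from_cm(cm)
  f <- 2 * p * r / (p + r)
  f[is.nan(f)] <- 0
  f
}

accuracy_from_cm <- function(cm) sum(diag(cm)) / sum(cm)

# AUC by the rank statistic (equivalent to the Wilcoxon/Mann-Whitney U):
# probability that a random positive scores above a random negative, ties
# counted half.
rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: evaluation set has one class")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a difficulty classifier
#'
#' Computes the confusion matrix on a labelled dataset and derives
#' per-class precision/recall/F1, accuracy, macro averages (unweighted
#' class means) and, for the binary task, AUC of the `difficult`-class
#' probability via the rank statistic.
#'
#' @param model A `trained_classifier`.
#' @param dataset List of samples with `image` and `outcome`.
#' @return `list(confusion =, per_class = data frame, accuracy =, auc =,
#'   macro = c(precision, recall, f1))`; `auc` is `NA` for the four-class
#'   task.
#' @export
evaluate_classifier <- function(model, dataset) {
  truth <- factor(dataset_labels(dataset, model$task), levels = model$levels)
  pred <- predict_difficulty(model, dataset)
  report_from_predictions(truth, pred$labels, pred$probs, model$levels,
                          model$task)
}

report_from_predictions <- function(truth, labels, probs, levels, task) {
  cm <- confusion_matrix(truth, labels, levels)
  per <- data.frame(class = levels,
                    precision = as.numeric(precision_from_cm(cm)),
                    recall = as.numeric(recall_from_cm(cm)),
                    f1 = as.numeric(f1_from_cm(cm)),
                    row.names = NULL)
  auc <- if (task == "binary") {
    rank_auc(probs[2, ], truth == "difficult")
  } else NA_real_
  list(confusion = cm, per_class = per,
       accuracy = accuracy_from_cm(cm), auc = auc,
       macro = c(precision = mean(per$precision),
                 recall = mean(per$recall),
                 f1 = mean(per$f1)))
}

# ---- cross-validation -------------------------------------------------

#' Stratified fold assignment
#'
#' Samples of each label are shuffled and dealt round-robin across folds,
#' so per-fold label counts differ from perfect proportionality by at most
#' one sample per class.
#'
#' @param labels Character or factor vector.
#' @param k Number of folds.
#' @param shuffle Shuffle within classes (uses the current RNG state).
#' @return Integer vector of fold ids in `1:k`, aligned with `labels`.
#' @export
stratified_folds <- function(labels, k, shuffle = TRUE) {
  n <- length(labels)
  if (k < 2) stop("need k >= 2 folds")
  if (k > n) stop("more folds than samples")
  fold <- integer(n)
  offset <- 0
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    if (shuffle) idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1 + offset) %% k) + 1
    offset <- offset + length(idx)  # stagger classes across folds
  }
  fold
}

#' Fivefold cross-validation harness for difficulty classification
#'
#' Stratified k-fold protocol: each sample sits in exactly one test fold;
#' for every fold a classifier is trained on the remainder and evaluated on
#' the held-out fold; all metrics are aggregated as mean and (population)
#' standard deviation across folds.
#'
#' @inheritParams train_difficulty_classifier
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment and per-fold training.
#' @return `list(folds = fold assignment, per_fold = list of reports,
#'   summary = data frame of mean/sd per metric)`.
#' @export
kfold_harness <- function(dataset, task = c("binary", "four_class"),
                          stop_metric = c("macro_f1", "accuracy"),
                          config = classifier_config(), k = 5, seed = 1L) {
  task <- match.arg(task)
  stop_metric <- match.arg(stop_metric)
  if (k > length(dataset)) stop("more folds than samples")
  set.seed(seed)
  labels <- dataset_labels(dataset, task)
  fold <- stratified_folds(labels, k)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    cfg <- config
    cfg$seed <- as.integer(seed + f)
    model <- train_difficulty_classifier(dataset[fold != f], task,
                                         stop_metric, cfg)
    reports[[f]] <- evaluate_classifier(model, dataset[fold == f])
  }
  metrics <- do.call(rbind, lapply(reports, function(r) {
    v <- c(accuracy = r$accuracy, macro_precision = r$macro[["precision"]],
           macro_recall = r$macro[["recall"]], macro_f1 = r$macro[["f1"]])
    if (task == "binary") v <- c(v, auc = r$auc)
    per <- r$per_class
    for (i in seq_len(nrow(per))) {
      v[paste0(per$class[i], "_precision")] <- per$precision[i]
      v[paste0(per$class[i], "_recall")] <- per$recall[i]
      v[paste0(per$class[i], "_f1")] <- per$f1[i]
    }
    v
  }))
  summary <- data.frame(metric = colnames(metrics),
                        mean = apply(metrics, 2, mean),
                        sd = apply(metrics, 2, sd_pop),
                        row.names = NULL)
  list(folds = fold, per_fold = reports, fold_metrics = metrics,
       summary = summary)
}
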