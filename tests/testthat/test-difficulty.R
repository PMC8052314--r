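test_that("outcome mapping covers the whole outcome space with precedence", {
  # exhaustive truth table over success x technique x time regimes,
  # including the exact 5-minute boundary
  for (tech in c(FALSE, TRUE)) {
    for (time_s in c(0, 130, 300, 300.5, 301, 1200)) {
      lab <- map_outcome(time_s, tech, TRUE)
      expected <- if (tech) "additional_technique"
                  else if (time_s > 300) "over_5min" else "easy"
      expect_equal(as.character(lab$four_class), expected)
      expect_equal(as.character(lab$binary),
                   if (expected == "easy") "easy" else "difficult")
      # failure dominates everything else
      flab <- map_outcome(time_s, tech, FALSE)
      expect_equal(as.character(flab$four_class), "failure")
      expect_equal(as.character(flab$binary), "difficult")
    }
  }
  expect_equal(as.character(map_outcome(NA, FALSE, FALSE)$four_class),
               "failure")
  expect_error(map_outcome(-5, FALSE, TRUE), "negative")
  expect_error(map_outcome(NA, FALSE, TRUE), "time")
  # boundary: exactly 5 minutes is easy, one second over is not
  expect_equal(as.character(map_outcome(300, FALSE, TRUE)$four_class), "easy")
  expect_equal(as.character(map_outcome(301, FALSE, TRUE)$four_class),
               "over_5min")
  # technique cases with long times stay in the technique class
  expect_equal(as.character(map_outcome(400, TRUE, TRUE)$four_class),
               "additional_technique")
})

test_that("classification metrics follow from the confusion matrix", {
  truth <- factor(c(rep("easy", 40), rep("difficult", 20)),
                  levels = c("easy", "difficult"))
  pred <- factor(c(rep("easy", 30), rep("difficult", 10),
                   rep("easy", 10), rep("difficult", 10)),
                 levels = c("easy", "difficult"))
  cm <- ampulla:::confusion_matrix(truth, pred, c("easy", "difficult"))
  expect_equal(as.numeric(cm), c(30, 10, 10, 10))
  rec <- ampulla:::recall_from_cm(cm)
  expect_equal(unname(rec), c(30 / 40, 10 / 20))
  expect_equal(ampulla:::accuracy_from_cm(cm), 40 / 60)
  prec <- ampulla:::precision_from_cm(cm)
  expect_equal(unname(prec), c(30 / 40, 10 / 20))
  f1 <- ampulla:::f1_from_cm(cm)
  expect_equal(unname(f1), 2 * prec * rec / (prec + rec), ignore_attr = TRUE)
  # macro-F1 is the unweighted mean of per-class F1
  expect_equal(mean(f1), (f1[[1]] + f1[[2]]) / 2)
})

test_that("rank-statistic AUC matches an independent implementation", {
  set.seed(51)
  scores <- runif(60)
  pos <- runif(60) < 0.4
  pos[1] <- TRUE; pos[2] <- FALSE  # both classes present
  a <- ampulla:::rank_auc(scores, pos)
  if (requireNamespace("pROC", quietly = TRUE)) {
    b <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores,
                                        quiet = TRUE, direction = "<")))
    expect_equal(a, b, tolerance = 1e-12)
  }
  # perfect separation
  expect_equal(ampulla:::rank_auc(c(0.1, 0.2, 0.8, 0.9),
                                  c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_error(ampulla:::rank_auc(runif(5), rep(TRUE, 5)), "one class")
})

test_that("perfect predictions score 1 on every metric", {
  truth <- factor(rep(difficulty_levels(), times = c(10, 5, 4, 2)),
                  levels = difficulty_levels())
  rep_ <- ampulla:::report_from_predictions(truth, truth,
                                            probs = NULL,
                                            levels = difficulty_levels(),
                                            task = "four_class")
  expect_equal(rep_$accuracy, 1)
  expect_equal(unname(rep_$macro), c(1, 1, 1))
  expect_true(all(rep_$per_class$f1 == 1))
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  set.seed(52)
  labels <- sample(difficulty_levels(), 103, replace = TRUE,
                   prob = c(0.6, 0.2, 0.15, 0.05))
  fold <- stratified_folds(labels, 5)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 103)
  # every sample in exactly one fold, proportions within one sample per class
  for (lv in unique(labels)) {
    counts <- table(factor(fold[labels == lv], levels = 1:5))
    expect_lte(diff(range(counts)), 1)
  }
  expect_error(stratified_folds(labels, 1), "k >= 2")
  expect_error(stratified_folds(labels[1:3], 5), "more folds")
})

test_that("classifier training is seed-reproducible and validates classes", {
  ds <- tiny_dataset(n = 60, seed = 5)
  cfg <- tiny_classifier_config(seed = 3)
  m1 <- train_difficulty_classifier(ds, "binary", "accuracy", cfg)
  m2 <- train_difficulty_classifier(ds, "binary", "accuracy", cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  # a dataset collapsed to one class cannot be trained
  easy_only <- generate_dataset(synth_config(n_images = 20, image_size = 32,
                                             class_mix = c(1, 0, 0, 0),
                                             seed = 6))
  expect_error(train_difficulty_classifier(easy_only, "binary", "accuracy",
                                           cfg),
               "at least 2")
})

test_that("stop_metric selects the epoch maximizing that metric", {
  ds <- tiny_dataset(n = 60, seed = 5)
  cfg <- tiny_classifier_config(seed = 3)
  cfg$max_epochs <- 4
  m <- train_difficulty_classifier(ds, "binary", "accuracy", cfg)
  expect_equal(max(m$log$val_metric), m$log$val_metric[m$best_epoch])
})

test_that("kfold harness partitions the data and aggregates fold metrics", {
  ds <- tiny_dataset(n = 50, seed = 7)
  res <- kfold_harness(ds, "binary", "accuracy",
                       tiny_classifier_config(), k = 3, seed = 2)
  expect_equal(length(res$folds), 50)
  expect_equal(sort(unique(res$folds)), 1:3)
  expect_equal(length(res$per_fold), 3)
  # the summary mean is the mean of per-fold metrics
  acc <- vapply(res$per_fold, `[[`, numeric(1), "accuracy")
  expect_equal(res$summary$mean[res$summary$metric == "accuracy"], mean(acc))
  expect_error(kfold_harness(ds[1:2], "binary", "accuracy",
                             tiny_classifier_config(), k = 5), "more folds")
})
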