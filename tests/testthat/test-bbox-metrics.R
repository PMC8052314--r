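test_that("iou matches hand-computed values", {
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(0, 0, 10, 10)), 1)
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(20, 20, 5, 5)), 0)
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10)), 50 / 150)
})

test_that("area precision/recall matches hand-computed values", {
  expect_equal(area_precision_recall(bbox(1, 1, 5, 5), bbox(1, 1, 5, 5)),
               c(precision = 1, recall = 1))
  # prediction fully containing the reference
  pr <- area_precision_recall(pred = bbox(0, 0, 20, 10), gt = bbox(5, 2, 10, 5))
  expect_equal(pr, c(precision = 50 / 200, recall = 1))
  expect_equal(area_precision_recall(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10)),
               c(precision = 0.5, recall = 0.5))
})

test_that("centroid distance follows its defining formula", {
  b <- bbox(10, 10, 20, 20)
  expect_equal(centroid_distance(b, b, 100, 100), 0)
  # centroids (50,50) and (60,70) on a 100x100 image
  g <- bbox(40, 40, 20, 20)
  e <- bbox(50, 60, 20, 20)
  expect_equal(centroid_distance(g, e, 100, 100), 0.5 * (10 / 100 + 20 / 100))
  # halving both image dimensions doubles the relative error
  expect_equal(centroid_distance(g, e, 50, 50),
               2 * centroid_distance(g, e, 100, 100))
  expect_error(centroid_distance(g, e, 0, 100), "positive")
})

test_that("metrics agree with the pixel-rasterization oracle", {
  set.seed(101)
  for (i in 1:1000) {
    W <- sample(20:64, 1); H <- sample(20:64, 1)
    a <- random_int_box(W, H)
    b <- random_int_box(W, H)
    o <- raster_metrics(a, b, W, H)
    expect_equal(iou(a, b), o$iou, tolerance = 1e-9)
    pr <- area_precision_recall(pred = b, gt = a)
    expect_equal(unname(pr["precision"]), o$precision, tolerance = 1e-9)
    expect_equal(unname(pr["recall"]), o$recall, tolerance = 1e-9)
  }
})

test_that("iou is symmetric, bounded, and dominated by precision and recall", {
  set.seed(7)
  for (i in 1:200) {
    a <- random_int_box(50, 50)
    b <- random_int_box(50, 50)
    v <- iou(a, b)
    expect_equal(v, iou(b, a))
    expect_gte(v, 0); expect_lte(v, 1)
    pr <- area_precision_recall(b, a)
    expect_lte(v, min(pr) + 1e-12)
    # identity iff identical boxes
    if (v == 1) expect_equal(as.numeric(a), as.numeric(b))
  }
})

test_that("centroid distance is translation-covariant", {
  set.seed(8)
  for (i in 1:50) {
    g <- bbox(runif(1, 0, 30), runif(1, 0, 30), runif(1, 1, 20), runif(1, 1, 20))
    e <- bbox(runif(1, 0, 30), runif(1, 0, 30), runif(1, 1, 20), runif(1, 1, 20))
    dx <- runif(1, -5, 5); dy <- runif(1, -5, 5)
    g2 <- bbox(g[["x"]] + dx, g[["y"]] + dy, g[["w"]], g[["h"]])
    e2 <- bbox(e[["x"]] + dx, e[["y"]] + dy, e[["w"]], e[["h"]])
    expect_equal(centroid_distance(g, e, 100, 80),
                 centroid_distance(g2, e2, 100, 80))
  }
})

test_that("success curves count strict threshold crossings", {
  ev <- data.frame(iou = c(0.2, 0.4, 0.6),
                   centroid_distance = c(0.005, 0.03, 0.2))
  expect_equal(success_rate(ev, "iou", 0.3), 2 / 3)
  expect_equal(success_rate(ev, "iou", 0), 1)
  expect_equal(success_rate(data.frame(centroid_distance = c(0.005, 0.03)),
                            "centroid_distance", 0.01), 0.5)
  expect_error(success_curve(ev, "mIoU"))
})

test_that("success curves are monotone in the threshold", {
  set.seed(9)
  ious <- runif(200)
  cds <- runif(200, 0, 0.2)
  ci <- success_curve(data.frame(iou = ious), "iou")
  expect_true(all(diff(ci$rate) <= 0))
  expect_equal(nrow(ci), 10)
  cc <- success_curve(data.frame(centroid_distance = cds), "centroid_distance")
  expect_true(all(diff(cc$rate) >= 0))
  expect_equal(cc$threshold, seq(0.01, 0.1, by = 0.01))
})

test_that("compare_annotations aggregates per-image metrics", {
  set.seed(10)
  a <- lapply(1:3, function(i) bbox(10 * i, 5 * i, 20, 15))
  b <- list(bbox(12, 6, 20, 15), bbox(18, 8, 25, 12), bbox(30, 15, 18, 20))
  res <- compare_annotations(a, b, c(100, 100))
  # identity comparison
  same <- compare_annotations(a, a, c(100, 100))
  expect_equal(unname(same$mean),
               c(1, 1, 1, 0))
  expect_equal(unname(same$sd), c(0, 0, 0, 0))
  # role swap exchanges precision and recall, preserves iou and distance
  swapped <- compare_annotations(b, a, c(100, 100))
  expect_equal(res$mean[["iou"]], swapped$mean[["iou"]])
  expect_equal(res$mean[["centroid_distance"]],
               swapped$mean[["centroid_distance"]])
  expect_equal(res$mean[["area_precision"]], swapped$mean[["area_recall"]])
  expect_equal(res$mean[["area_recall"]], swapped$mean[["area_precision"]])
  # means equal the average of independently computed per-image values
  per <- sapply(1:3, function(i) iou(a[[i]], b[[i]]))
  expect_equal(res$mean[["iou"]], mean(per))
  expect_error(compare_annotations(a, b[1:2], c(100, 100)), "equal length")
})
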