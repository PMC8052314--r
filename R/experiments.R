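#' Default synthetic detection benchmark
#'
#' Generates disjoint train and test sets of endoscopy-like images at the
#' desk-scale benchmark size: 600 training and 200 test images of 64 x 64
#' pixels by default.
#'
#' @param n_train,n_test Split sizes.
#' @param image_size Image side in pixels.
#' @param seed Integer seed; the test set uses a fixed offset of the seed
#'   so train and test never share RNG streams.
#' @param ... Further [synth_config()] overrides.
#' @return `list(train =, test =)` datasets.
#' @export
synth_detection_benchmark <- function(n_train = 600, n_test = 200,
                                      image_size = 64, seed = 1L, ...) {
  list(train = generate_dataset(synth_config(n_images = n_train,
                                             image_size = image_size,
                                             seed = seed, ...)),
       test = generate_dataset(synth_config(n_images = n_test,
                                            image_size = image_size,
                                            seed = seed + 100003L, ...)))
}

# benchmark-scale detector configurations: small networks that train on one
# CPU in about a minute per run. The two models get separate optimizer
# budgets because they converge at different speeds: the soft-mask U-Net
# fits the dense BCE target within a handful of epochs, while the sparse
# 4-number regression target needs a higher learning rate and more epochs
# to leave its regress-to-the-mean plateau.
benchmark_detector_config <- function(image_size = 64, seed = 1L,
                                      model = c("soft_mask", "bbox")) {
  model <- match.arg(model)
  if (model == "soft_mask") {
    detector_config(input_size = image_size, base_channels = 8, depth = 3,
                    learning_rate = 2e-3, max_epochs = 8,
                    early_stop_patience = 3, batch_size = 16, seed = seed)
  } else {
    detector_config(input_size = image_size, base_channels = 8, depth = 3,
                    learning_rate = 5e-3, max_epochs = 25,
                    early_stop_patience = 8, batch_size = 16, seed = seed)
  }
}

#' Run the detection experiment end to end
#'
#' For each seed: generate (or reuse) a synthetic benchmark, train the
#' soft-mask detector and the bbox-regressor baseline, evaluate both on the
#' held-out test set, and build success curves for IoU and centroid
#' distance. Aggregates are means with population standard deviation across
#' seeds. Reruns with identical arguments are bit-identical.
#'
#' @param seeds Integer vector of seeds, one independent run per seed.
#' @param n_train,n_test,image_size Benchmark sizes, see
#'   [synth_detection_benchmark()].
#' @param models Subset of `c("soft_mask", "bbox")`.
#' @param config Optional [detector_config()]; defaults to the benchmark
#'   configuration (seed overridden per run).
#' @param out_dir If non-`NULL`, per-image metrics and curves are written
#'   there as CSV plus success-plot PNGs and a JSON report.
#' @return List with `per_seed` (per-model evaluation tables), `summary`
#'   (mean/sd of mIoU, precision, recall, centroid distance,
#'   success@IoU0.3, success@cd0.05 per model) and `curves` (averaged
#'   success curves per model/metric).
#' @export
run_detection_experiment <- function(seeds = 1L, n_train = 600, n_test = 200,
                                     image_size = 64,
                                     models = c("soft_mask", "bbox"),
                                     config = NULL, out_dir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  per_seed <- list()
  for (seed in seeds) {
    bench <- synth_detection_benchmark(n_train, n_test, image_size, seed)
    run <- list(seed = seed)
    for (m in models) {
      cfg <- if (is.null(config)) benchmark_detector_config(image_size, seed, m)
             else { config$seed <- as.integer(seed); config }
      model <- if (m == "soft_mask") train_soft_mask_detector(bench$train, cfg)
               else train_bbox_regressor(bench$train, cfg)
      run[[m]] <- evaluate_detector(model, bench$test)
    }
    per_seed[[as.character(seed)]] <- run
  }

  summarize <- function(m) {
    rows <- lapply(per_seed, function(run) {
      ev <- run[[m]]
      c(miou = mean(ev$iou),
        area_precision = mean(ev$area_precision),
        area_recall = mean(ev$area_recall),
        centroid_distance = mean(ev$centroid_distance),
        success_iou_0.3 = success_rate(ev, "iou", 0.3),
        success_cd_0.05 = success_rate(ev, "centroid_distance", 0.05))
    })
    tab <- do.call(rbind, rows)
    data.frame(model = m, metric = colnames(tab),
               mean = apply(tab, 2, mean), sd = apply(tab, 2, sd_pop),
               row.names = NULL)
  }
  summary <- do.call(rbind, lapply(models, summarize))

  curves <- list()
  for (m in models) {
    for (metric in c("iou", "centroid_distance")) {
      cs <- lapply(per_seed, function(run) success_curve(run[[m]], metric))
      avg <- cs[[1]]
      avg$rate <- rowMeans(vapply(cs, `[[`, numeric(nrow(avg)), "rate"))
      curves[[paste(m, metric, sep = "_")]] <- avg
    }
  }

  report <- list(per_seed = per_seed, summary = summary, curves = curves)
  if (!is.null(out_dir)) write_detection_report(report, out_dir, models)
  report
}

write_detection_report <- function(report, out_dir, models) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(report$per_seed)) {
    for (m in models) {
      utils::write.csv(report$per_seed[[s]][[m]],
                       file.path(out_dir,
                                 sprintf("per_image_%s_seed%s.csv", m, s)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  for (nm in names(report$curves))
    write_success_curve(report$curves[[nm]],
                        file.path(out_dir, paste0("curve_", nm, ".csv")))
  for (metric in c("iou", "centroid_distance")) {
    sel <- report$curves[grepl(paste0("_", metric, "$"), names(report$curves))]
    names(sel) <- sub(paste0("_", metric, "$"), "", names(sel))
    plot_success_curves(sel, file.path(out_dir,
                                       paste0("success_", metric, ".png")),
                        main = paste("Success plot:", metric))
  }
  jsonlite::write_json(list(summary = report$summary),
                       file.path(out_dir, "report.json"),
                       dataframe = "rows", digits = NA)
  invisible(out_dir)
}

#' Compare model detections with a second annotator
#'
#' Mirrors the three-way inter-annotator protocol: a seeded random sample
#' of test images is scored as model vs reference labels, annotator B vs
#' reference, and model vs annotator B (B as the reference). Sampled
#' indices are returned so the comparison is reproducible.
#'
#' @param dataset Test dataset (samples with `image` and `gt_box`).
#' @param model A `trained_detector`.
#' @param annotations_b List of boxes index-aligned with `dataset`.
#' @param n_sample Number of images to sample (default 30).
#' @param seed Sampling seed.
#' @return List with `indices` and three [compare_annotations()] results:
#'   `model_vs_gt`, `b_vs_gt`, `model_vs_b`.
#' @export
run_human_comparison <- function(dataset, model, annotations_b,
                                 n_sample = 30, seed = 1L) {
  if (length(annotations_b) != length(dataset))
    stop("annotations_b must be index-aligned with the dataset")
  set.seed(seed)
  idx <- sort(sample.int(length(dataset), min(n_sample, length(dataset))))
  gt <- lapply(dataset[idx], function(s) as_bbox(s$gt_box))
  bb <- lapply(annotations_b[idx], as_bbox)
  pred <- lapply(dataset[idx], function(s) predict_box(model, s$image)$box)
  sizes <- lapply(dataset[idx], function(s)
    c(dim(s$image)[2], dim(s$image)[1]))
  list(indices = idx,
       model_vs_gt = compare_annotations(gt, pred, sizes),
       b_vs_gt = compare_annotations(gt, bb, sizes),
       model_vs_b = compare_annotations(bb, pred, sizes))
}

#' Run the difficulty-classification experiment
#'
#' Each configuration (task x stopping metric, optionally different
#' architectures) goes through the stratified k-fold harness on the same
#' dataset; the comparison table marks the best configuration per metric.
#'
#' @param dataset Labelled dataset (samples with `image` and `outcome`).
#' @param task `"binary"` or `"four_class"`.
#' @param stop_metrics Stopping-metric variants to compare.
#' @param config Base [classifier_config()].
#' @param k Folds.
#' @param seed Harness seed.
#' @param out_dir Optional report directory (CSV + JSON).
#' @return List with `runs` (one [kfold_harness()] result per
#'   configuration), `table` (configurations x metric means) and `best`
#'   (per-metric argmax configuration).
#' @export
run_classification_experiment <- function(dataset,
                                          task = c("binary", "four_class"),
                                          stop_metrics = c("macro_f1",
                                                           "accuracy"),
                                          config = classifier_config(),
                                          k = 5, seed = 1L, out_dir = NULL) {
  task <- match.arg(task)
  runs <- list()
  for (sm in stop_metrics) {
    runs[[sm]] <- kfold_harness(dataset, task, sm, config, k = k, seed = seed)
  }
  metrics <- Reduce(intersect, lapply(runs, function(r) r$summary$metric))
  table <- do.call(rbind, lapply(names(runs), function(nm) {
    s <- runs[[nm]]$summary
    row <- s$mean[match(metrics, s$metric)]
    names(row) <- metrics
    data.frame(config = nm, t(row), check.names = FALSE)
  }))
  best <- vapply(metrics, function(m)
    table$config[which.max(table[[m]])], character(1))
  out <- list(runs = runs, table = table, best = best)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "classification_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(table = table, best = as.list(best)),
                         file.path(out_dir, "classification_report.json"),
                         dataframe = "rows", digits = NA)
  }
  out
}
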