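# ampulla

Toolkit for two computational tasks behind AI-assisted ERCP (endoscopic
retrograde cholangiopancreatography): **localizing the ampulla of Vater
(AOV)** in endoscopic images and **grading the expected difficulty of
selective biliary cannulation**. It is aimed at researchers building or
evaluating endoscopy-assistance models who need the full pipeline —
label encoding, training, decoding, metrics, cross-validation — in a
reproducible, CPU-friendly form.

## The method

Instead of regressing box coordinates directly, a bounding-box annotation
`(x, y, w, h)` is encoded as a *soft mask*: an axis-aligned bivariate
Gaussian with mean at the box centroid, peak value 1 and spread tied to the
box extent (default σₓ = w/2, σᵧ = h/2),

```
M(i, j) = exp(-½ [((j+½-μx)/σx)² + ((i+½-μy)/σy)²]).
```

A compact U-Net-style encoder–decoder is trained against these masks with
binary cross-entropy; at evaluation time the predicted mask is
peak-normalized, thresholded at 0.6, and the connected component containing
the peak is converted back to a tight box. Detections are scored per image
by IoU, area precision/recall, the relative centroid distance
`½(|xg-xe|/W + |yg-ye|/H)`, and success plots over threshold sweeps. A
direct bbox-regression baseline (same encoder, MAE loss) is built in for
comparison.

For difficulty grading, procedural outcomes (cannulation time, use of
additional techniques, success) map to labels with precedence
`failure > additional_technique > over_5min > easy` (strict 5-minute rule),
and a small CNN classifier is trained and evaluated under stratified
fivefold cross-validation with per-class precision/recall/F1, accuracy,
macro averages and rank-statistic AUC (binary).

Everything runs on a built-in seeded generator of endoscopy-like synthetic
images (one bright ellipse-like target on a cluttered background, with
difficulty-linked visual features), so no patient data is required to
exercise or test any component.

## Worked example

```r
library(ampulla)

bench <- synth_detection_benchmark(seed = 1)   # 600 train / 200 test, 64x64
model <- train_soft_mask_detector(
  bench$train,
  detector_config(input_size = 64, base_channels = 8,
                  learning_rate = 2e-3, max_epochs = 8,
                  early_stop_patience = 3, seed = 1))
ev <- evaluate_detector(model, bench$test)
round(colMeans(ev), 3)
#>               iou    area_precision       area_recall centroid_distance
#>             0.647             0.653             0.992             0.007
success_rate(ev, "iou", 0.3)
#> [1] 1
```

The mean IoU of 0.647 says predicted boxes overlap the reference by about
two-thirds on average — decoded boxes hug the 0.6 probability level set of
the predicted mask and tend to be slightly inflated, which also explains
the high area recall (0.992) against the lower area precision (0.653) —
while the success rate of 1.0 at IoU 0.3 and the centroid distance of 0.007
(0.7% of the image side) say the ampulla is essentially always found and
precisely localized. Training takes about a
minute on one CPU.

One prediction:

```r
pred <- predict_box(model, bench$test[[1]]$image)
pred$box
#> <bbox x=23 y=0 w=35 h=22>
bench$test[[1]]$gt_box
#> <bbox x=23.093 y=1.502 w=35.02 h=17.844>
```

Difficulty classification, fivefold:

```r
ds <- generate_dataset(synth_config(n_images = 1000, seed = 1))
cv <- kfold_harness(ds, task = "binary", stop_metric = "macro_f1",
                    k = 5, seed = 1)
subset(cv$summary, metric %in% c("accuracy", "macro_f1", "auc"))
```

## Command line

A thin CLI over the same functions lives at `inst/cli/ercp-toolkit.R`
(verbs: `simulate`, `render`, `decode`, `train-detect`, `predict`,
`train-classify`, `eval-detect`, `eval-classify`, `compare-annotators`),
e.g.

```sh
Rscript inst/cli/ercp-toolkit.R simulate --out fixtures --seed 7
Rscript inst/cli/ercp-toolkit.R train-detect --data fixtures --out run.rds
```

See the vignette (`vignettes/soft-mask-detection.Rmd`) for the model,
its assumptions, parameter meanings and known limitations.
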