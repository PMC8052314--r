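test_that("generation is deterministic given the seed", {
  cfg <- synth_config(n_images = 8, image_size = 48, seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(synth_config(n_images = 8, image_size = 48,
                                      seed = 78))
  expect_false(identical(d1, d3))
})

test_that("degenerate class mixes produce the requested outcomes", {
  easy_only <- generate_dataset(synth_config(n_images = 12, image_size = 32,
                                             class_mix = c(1, 0, 0, 0),
                                             seed = 3))
  labs <- vapply(easy_only, function(s)
    as.character(map_outcome(s$outcome$cannulation_time_s,
                             s$outcome$additional_technique,
                             s$outcome$success)$four_class), character(1))
  expect_true(all(labs == "easy"))
})

test_that("outcome sampling is consistent with the latent class", {
  ds <- generate_dataset(synth_config(n_images = 150, image_size = 32,
                                      seed = 14,
                                      class_mix = c(0.25, 0.25, 0.25, 0.25)))
  for (s in ds) {
    lab <- map_outcome(s$outcome$cannulation_time_s,
                       s$outcome$additional_technique, s$outcome$success)
    expect_equal(as.character(lab$four_class), s$latent$class)
  }
  # failure outcomes carry no cannulation time
  fails <- Filter(function(s) s$latent$class == "failure", ds)
  expect_true(all(vapply(fails, function(s)
    is.na(s$outcome$cannulation_time_s), logical(1))))
})

test_that("class proportions converge to the configured mix", {
  mix <- c(easy = 0.68, over_5min = 0.13, additional_technique = 0.18,
           failure = 0.01)
  cfg <- synth_config(n_images = 2000, image_size = 16,
                      difficulty_feature_strength = 1, seed = 15)
  classes <- vapply(generate_dataset(cfg), function(s) s$latent$class,
                    character(1))
  freq <- table(factor(classes, levels = names(mix))) / 2000
  expect_true(all(abs(freq - mix) <= 0.03))
  # a chi-squared test against the target mix does not reject at alpha 0.01
  p <- stats::chisq.test(table(factor(classes, levels = names(mix))),
                         p = mix)$p.value
  expect_gt(p, 0.01)
})

test_that("the target blob is bright, boxed tightly and learnable", {
  ds <- generate_dataset(synth_config(n_images = 30, image_size = 64,
                                      seed = 16))
  for (s in ds) {
    S <- 64
    lat <- s$latent
    x <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE)
    y <- matrix(seq_len(S) - 0.5, S, S)
    inside <- ((x - lat$cx) / lat$ax)^2 + ((y - lat$cy) / lat$ay)^2 <= 1
    gray <- s$image[, , 1]
    margin <- mean(gray[inside]) - mean(gray[!inside])
    expect_gte(margin, 40 / 255)
    # the gt box is the tight box of the support ellipse
    expect_equal(s$gt_box[["w"]], 2 * lat$ax, tolerance = 1e-3)
    expect_equal(s$gt_box[["h"]], 2 * lat$ay, tolerance = 1e-3)
    expect_true(bbox_in_image(s$gt_box, S, S))
    # the soft-mask peak falls inside the blob's support
    m <- unclass(render_soft_mask(s$gt_box, S, S))
    pk <- which(m == max(m), arr.ind = TRUE)[1, ]
    expect_true(inside[pk[1], pk[2]])
  }
})

test_that("fixtures round-trip boxes, outcomes and pixel values", {
  ds <- generate_dataset(synth_config(n_images = 6, image_size = 32,
                                      seed = 17))
  dir <- tempfile()
  write_fixture(dir, ds)
  expect_equal(length(list.files(file.path(dir, "images"))), 6)
  back <- read_fixture(dir)
  expect_equal(length(back), 6)
  for (i in seq_along(ds)) {
    expect_equal(as.numeric(back[[i]]$gt_box), as.numeric(ds[[i]]$gt_box))
    expect_identical(back[[i]]$outcome$success, ds[[i]]$outcome$success)
    expect_identical(back[[i]]$outcome$additional_technique,
                     ds[[i]]$outcome$additional_technique)
    expect_equal(back[[i]]$outcome$cannulation_time_s,
                 ds[[i]]$outcome$cannulation_time_s)
    # 8-bit PNG is lossless for the quantized images
    expect_equal(back[[i]]$image, ds[[i]]$image, tolerance = 1e-9)
  }
  # both annotation dialects agree
  ja <- read_annotations(file.path(dir, "annotations.json"))
  ca <- read_annotations(file.path(dir, "annotations.csv"))
  expect_equal(lapply(ja, as.numeric), lapply(ca, as.numeric))
})
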