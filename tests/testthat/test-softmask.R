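test_that("rendered mask peaks at the centroid with closed-form falloff", {
  # centroid (64.5, 64.5) sits exactly on the centre of pixel (65, 65)
  b <- bbox(44.5, 34.5, 40, 60)  # sx = 20, sy = 30
  m <- render_soft_mask(b, 128, 128)
  expect_s3_class(m, "soft_mask")
  expect_equal(m[65, 65], 1)                      # peak value 1 at the mean
  expect_true(all(unclass(m) <= m[65, 65]))
  expect_equal(m[65, 85], exp(-0.5))              # one sigma_x to the right
  expect_equal(m[95, 65], exp(-0.5))              # one sigma_y down
})

test_that("sigma scales with box extent: doubling w doubles level-set reach", {
  m1 <- render_soft_mask(bbox(54, 54, 20, 20), 128, 128)
  m2 <- render_soft_mask(bbox(44, 54, 40, 20), 128, 128)
  # distance (in columns) at which the peak row drops below 0.6
  reach <- function(m) {
    row <- m[64, ]
    max(which(row > 0.6)) - 64
  }
  expect_equal(reach(m2), 2 * reach(m1), tolerance = 0.15)
})

test_that("rendered values decrease monotonically away from the peak", {
  m <- render_soft_mask(bbox(30.5, 40.5, 30, 20), 96, 96)
  pk <- which(unclass(m) == max(m), arr.ind = TRUE)[1, ]
  row <- m[pk[1], ]
  col <- m[, pk[2]]
  expect_true(all(diff(row[pk[2]:96]) < 0))
  expect_true(all(diff(rev(row[1:pk[2]])) < 0))
  expect_true(all(diff(col[pk[1]:96]) < 0))
  # reflection symmetry about the centroid (up to half-pixel grid effects)
  b <- bbox(28, 28, 40, 40)  # centroid (48, 48) on pixel corner grid
  ms <- render_soft_mask(b, 96, 96)
  expect_equal(unclass(ms), unclass(ms)[96:1, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(ms), unclass(ms)[, 96:1], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("var_half_extent mode uses sqrt(w/2) spread", {
  b <- bbox(44.5, 44.5, 40, 40)  # centroid on the centre of pixel (65, 65)
  m <- render_soft_mask(b, 128, 128, sigma_mode = "var_half_extent")
  sx <- sqrt(20)
  expect_equal(m[65, 65], 1)
  expect_equal(m[65, 85], exp(-0.5 * (20 / sx)^2))
  # much tighter than the std_half_extent rendering of the same box
  ms <- render_soft_mask(b, 128, 128, sigma_mode = "std_half_extent")
  expect_lt(m[65, 85], ms[65, 85])
})

test_that("decoding recovers simple masks", {
  m <- matrix(0, 20, 20)
  m[7, 13] <- 1
  b <- decode_mask_to_bbox(m)
  expect_equal(as.numeric(b), c(12, 6, 1, 1))
  expect_error(decode_mask_to_bbox(matrix(0, 5, 5)), "no detection")
  expect_error(decode_mask_to_bbox(matrix(1, 5, 5), threshold = 1.2))
})

test_that("decoding keeps only the component of the strongest peak", {
  m <- matrix(0, 64, 64)
  g1 <- render_soft_mask(bbox(10, 10, 12, 12), 64, 64)        # peak 1.0
  g2 <- 0.8 * render_soft_mask(bbox(40, 40, 12, 12), 64, 64)  # peak 0.8
  m <- pmax(unclass(g1), unclass(g2))
  dec <- decode_mask_to_bbox(m, threshold = 0.6)
  # oracle: BFS component around the global peak on the thresholded mask
  pk <- which(m == max(m), arr.ind = TRUE)[1, ]
  ob <- bfs_component_box(m > 0.6, pk[1], pk[2])
  expect_equal(as.numeric(dec), unname(ob))
  # the stronger bump lives near (16, 16): its component, not the 0.8 one
  expect_lt(dec[["x"]] + dec[["w"]], 35)
})

test_that("decode is scale-invariant and never drops the peak pixel", {
  set.seed(21)
  for (i in 1:20) {
    b <- bbox(runif(1, 5, 60), runif(1, 5, 60), runif(1, 8, 30), runif(1, 8, 30))
    m <- unclass(render_soft_mask(b, 100, 100))
    d1 <- decode_mask_to_bbox(m)
    d2 <- decode_mask_to_bbox(m * runif(1, 0.05, 50))
    expect_equal(as.numeric(d1), as.numeric(d2))
    pk <- which(m == max(m), arr.ind = TRUE)[1, ]
    expect_true(pk[2] - 1 >= d1[["x"]] && pk[2] <= d1[["x"]] + d1[["w"]])
    expect_true(pk[1] - 1 >= d1[["y"]] && pk[1] <= d1[["y"]] + d1[["h"]])
  }
})

test_that("render/decode round trip recovers boxes near the 0.6 level set", {
  set.seed(22)
  n <- 200
  ratios <- numeric(0)
  for (i in 1:n) {
    frac <- runif(1, 0.05, 0.5)        # box area as fraction of the image
    aspect <- runif(1, 0.6, 1.6)
    w <- sqrt(128^2 * frac * aspect)
    h <- 128^2 * frac / w
    x <- runif(1, 0, 128 - w); y <- runif(1, 0, 128 - h)
    b <- bbox(x, y, w, h)
    dec <- decode_mask_to_bbox(unclass(render_soft_mask(b, 128, 128)), 0.6)
    expect_gt(iou(b, dec), 0.9)
    expect_lt(centroid_distance(b, dec, 128, 128), 0.01)
    ratios <- c(ratios, dec[["w"]] / w)
  }
  # mean width inflation tracks the analytic level-set factor sqrt(-2 ln 0.6)
  expect_gt(mean(ratios), 1.0)
  expect_lt(mean(ratios), 1.03)
})

test_that("bce loss has its closed-form values and invariances", {
  u <- matrix(0.5, 8, 8)
  expect_equal(bce_loss(u, u), log(2))
  set.seed(23)
  t <- matrix(runif(64), 8, 8)
  # minimized when pred equals target
  expect_lt(bce_loss(t, t), bce_loss(pmin(pmax(t + 0.1, 0), 1), t))
  expect_lt(bce_loss(t, t), bce_loss(matrix(0.5, 8, 8), t))
  # permutation invariance over pixels
  perm <- sample(64)
  p <- matrix(runif(64), 8, 8)
  expect_equal(bce_loss(p, t),
               bce_loss(matrix(p[perm], 8, 8), matrix(t[perm], 8, 8)))
  expect_error(bce_loss(matrix(0.5, 4, 4), matrix(0.5, 5, 5)), "shape")
})

test_that("masks round-trip through RDS and quantize predictably through PNG", {
  m <- render_soft_mask(bbox(10, 10, 20, 14), 48, 48)
  rds <- tempfile(fileext = ".rds")
  png <- tempfile(fileext = ".png")
  write_mask(m, rds)
  write_mask(m, png)
  expect_identical(unclass(read_mask(rds)), unclass(m), ignore_attr = TRUE)
  expect_equal(unclass(read_mask(png)), round(255 * unclass(m)) / 255,
               tolerance = 1e-9, ignore_attr = TRUE)
})
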