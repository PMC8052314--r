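# Independent oracles used across tests. These deliberately avoid the
# package's own closed-form code paths: boxes are painted onto pixel grids
# and metrics counted, connected components are grown by plain BFS in R.

# paint an integer box (0-based, half-open [x, x+w) x [y, y+h)) on a grid
paint_box <- function(b, W, H) {
  g <- matrix(FALSE, H, W)
  cols <- seq.int(b[1] + 1, b[1] + b[3])
  rows <- seq.int(b[2] + 1, b[2] + b[4])
  g[rows, cols] <- TRUE
  g
}

# pixel-counting metrics for integer boxes
raster_metrics <- function(a, b, W, H) {
  ga <- paint_box(a, W, H)
  gb <- paint_box(b, W, H)
  inter <- sum(ga & gb)
  union <- sum(ga | gb)
  list(iou = inter / union,
       precision = inter / sum(gb),   # b as the prediction
       recall = inter / sum(ga))
}

# random integer box fitting in a W x H image, with w, h >= 1
random_int_box <- function(W, H, max_frac = 0.8) {
  w <- sample.int(max(1, floor(W * max_frac)), 1)
  h <- sample.int(max(1, floor(H * max_frac)), 1)
  x <- sample.int(W - w + 1, 1) - 1
  y <- sample.int(H - h + 1, 1) - 1
  c(x, y, w, h)
}

# BFS connected component of `mask` containing (pi, pj); returns the tight
# 0-based bbox, independent of the package's flood fill
bfs_component_box <- function(mask, pi, pj, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  seen <- matrix(FALSE, H, W)
  queue <- list(c(pi, pj))
  seen[pi, pj] <- TRUE
  cells <- matrix(c(pi, pj), 1, 2)
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (t in seq_len(nrow(nb))) {
      ni <- cur[1] + nb[t, 1]; nj <- cur[2] + nb[t, 2]
      if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
          !seen[ni, nj] && mask[ni, nj]) {
        seen[ni, nj] <- TRUE
        queue <- c(queue, list(c(ni, nj)))
        cells <- rbind(cells, c(ni, nj))
      }
    }
  }
  c(x = min(cells[, 2]) - 1, y = min(cells[, 1]) - 1,
    w = diff(range(cells[, 2])) + 1, h = diff(range(cells[, 1])) + 1)
}

# tiny synthetic dataset for fast training smoke tests
tiny_dataset <- function(n = 40, size = 32, seed = 123) {
  generate_dataset(synth_config(n_images = n, image_size = size, seed = seed))
}

tiny_detector_config <- function(seed = 1, ...) {
  detector_config(input_size = 32, base_channels = 4, depth = 2,
                  max_epochs = 2, early_stop_patience = 2, batch_size = 8,
                  seed = seed, ...)
}

tiny_classifier_config <- function(seed = 1, ...) {
  classifier_config(input_size = 32, base_channels = 4, depth = 2,
                    max_epochs = 2, early_stop_patience = 2, batch_size = 8,
                    seed = seed, ...)
}
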