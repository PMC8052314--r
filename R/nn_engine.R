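# Compact CNN engine. Parameters live in a flat named list of R arrays;
# forward/backward passes compose the C++ primitives (im2col convolution,
# 2x2 max pool, nearest upsample). All tensors are (H, W, C, N) arrays.
# Randomness is drawn from R's RNG only, so set.seed() fixes everything.

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

conv_param <- function(k, cin, cout) {
  list(w = he_init(k, cin, cout), b = numeric(cout))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# channel widths for an encoder of given depth
enc_channels <- function(base, depth) base * 2^(seq_len(depth) - 1)

#' @keywords internal
unet_init <- function(in_ch, base, depth) {
  ch <- enc_channels(base, depth)
  p <- list()
  cin <- in_ch
  for (d in seq_len(depth)) {
    p[[paste0("enc", d)]] <- conv_param(3, cin, ch[d])
    cin <- ch[d]
  }
  p$bott <- conv_param(3, ch[depth], 2 * ch[depth])
  prev <- 2 * ch[depth]
  for (d in rev(seq_len(depth))) {
    p[[paste0("dec", d)]] <- conv_param(3, prev, ch[d])
    prev <- ch[d]
  }
  p$out <- conv_param(1, ch[1], 1)
  p
}

# U-Net forward: encoder conv+pool stages, bottleneck, decoder with
# additive skip connections, 1x1 output conv producing logits.
unet_fw <- function(p, x, depth) {
  cache <- list(enc_in = list(), a = list(), idx = list(),
                dec_in = list(), dec_r = list())
  cur <- x
  for (d in seq_len(depth)) {
    cache$enc_in[[d]] <- cur
    a <- relu(nn_conv_fw(cur, p[[paste0("enc", d)]]$w,
                         p[[paste0("enc", d)]]$b, 1L))
    mp <- nn_maxpool_fw(a)
    cache$a[[d]] <- a
    cache$idx[[d]] <- mp$idx
    cur <- mp$y
  }
  cache$bott_in <- cur
  b <- relu(nn_conv_fw(cur, p$bott$w, p$bott$b, 1L))
  cache$b <- b
  cur <- b
  for (d in rev(seq_len(depth))) {
    u <- nn_upsample_fw(cur)
    cache$dec_in[[d]] <- u
    r <- relu(nn_conv_fw(u, p[[paste0("dec", d)]]$w,
                         p[[paste0("dec", d)]]$b, 1L))
    cache$dec_r[[d]] <- r
    cur <- r + cache$a[[d]]
  }
  cache$out_in <- cur
  logit <- nn_conv_fw(cur, p$out$w, p$out$b, 0L)
  list(logit = logit, cache = cache)
}

unet_bw <- function(p, cache, glogit, depth) {
  g <- list()
  bw <- nn_conv_bw(cache$out_in, p$out$w, glogit, 0L)
  g$out <- list(w = bw$gw, b = bw$gb)
  gcur <- bw$gx
  gskip <- list()
  for (d in seq_len(depth)) {        # reverse of decoder execution order
    gskip[[d]] <- gcur
    gz <- gcur * (cache$dec_r[[d]] > 0)
    bw <- nn_conv_bw(cache$dec_in[[d]], p[[paste0("dec", d)]]$w, gz, 1L)
    g[[paste0("dec", d)]] <- list(w = bw$gw, b = bw$gb)
    gcur <- nn_upsample_bw(bw$gx)
  }
  gz <- gcur * (cache$b > 0)
  bw <- nn_conv_bw(cache$bott_in, p$bott$w, gz, 1L)
  g$bott <- list(w = bw$gw, b = bw$gb)
  gcur <- bw$gx
  for (d in rev(seq_len(depth))) {
    ga <- nn_maxpool_bw(gcur, cache$idx[[d]], dim(cache$a[[d]])) + gskip[[d]]
    gz <- ga * (cache$a[[d]] > 0)
    bw <- nn_conv_bw(cache$enc_in[[d]], p[[paste0("enc", d)]]$w, gz, 1L)
    g[[paste0("enc", d)]] <- list(w = bw$gw, b = bw$gb)
    gcur <- bw$gx
  }
  g
}

#' @keywords internal
encoder_init <- function(in_ch, base, depth, n_out) {
  ch <- enc_channels(base, depth)
  p <- list()
  cin <- in_ch
  for (d in seq_len(depth)) {
    p[[paste0("enc", d)]] <- conv_param(3, cin, ch[d])
    cin <- ch[d]
  }
  p$bott <- conv_param(3, ch[depth], 2 * ch[depth])
  feat <- 2 * ch[depth]
  p$fc <- list(w = matrix(stats::rnorm(n_out * feat, sd = sqrt(1 / feat)),
                          n_out, feat),
               b = numeric(n_out))
  p
}

# encoder + global average pooling + linear head; returns raw scores (K x N)
encoder_fw <- function(p, x, depth) {
  cache <- list(enc_in = list(), a = list(), idx = list())
  cur <- x
  for (d in seq_len(depth)) {
    cache$enc_in[[d]] <- cur
    a <- relu(nn_conv_fw(cur, p[[paste0("enc", d)]]$w,
                         p[[paste0("enc", d)]]$b, 1L))
    mp <- nn_maxpool_fw(a)
    cache$a[[d]] <- a
    cache$idx[[d]] <- mp$idx
    cur <- mp$y
  }
  cache$bott_in <- cur
  b <- relu(nn_conv_fw(cur, p$bott$w, p$bott$b, 1L))
  cache$b <- b
  db <- dim(b)
  feat <- matrix(colMeans(matrix(b, db[1] * db[2], db[3] * db[4])),
                 db[3], db[4])
  cache$feat <- feat
  scores <- p$fc$w %*% feat + p$fc$b
  list(scores = scores, cache = cache)
}

encoder_bw <- function(p, cache, gscores, depth) {
  g <- list()
  g$fc <- list(w = gscores %*% t(cache$feat), b = rowSums(gscores))
  gfeat <- t(p$fc$w) %*% gscores
  db <- dim(cache$b)
  gb <- array(rep(as.numeric(gfeat), each = db[1] * db[2]) / (db[1] * db[2]),
              dim = db)
  gz <- gb * (cache$b > 0)
  bw <- nn_conv_bw(cache$bott_in, p$bott$w, gz, 1L)
  g$bott <- list(w = bw$gw, b = bw$gb)
  gcur <- bw$gx
  for (d in rev(seq_len(depth))) {
    ga <- nn_maxpool_bw(gcur, cache$idx[[d]], dim(cache$a[[d]]))
    gz <- ga * (cache$a[[d]] > 0)
    bw <- nn_conv_bw(cache$enc_in[[d]], p[[paste0("enc", d)]]$w, gz, 1L)
    g[[paste0("enc", d)]] <- list(w = bw$gw, b = bw$gb)
    gcur <- bw$gx
  }
  g
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(p) lapply(p, function(a) a * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      gr <- grads[[nm]][[f]]
      state$m[[nm]][[f]] <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * gr
      state$v[[nm]][[f]] <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * gr^2
      mhat <- state$m[[nm]][[f]] / bc1
      vhat <- state$v[[nm]][[f]] / bc2
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# stack a list of (H, W, C) arrays into an (H, W, C, N) batch
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  if (length(d) == 2) d <- c(d, 1)
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

#' Resize an image array by bilinear interpolation
#'
#' @param img `H x W x C` (or `H x W`) numeric array with values in `[0, 1]`.
#' @param out_h,out_w Target size in pixels.
#' @return Resized array.
#' @export
resize_image <- function(img, out_h, out_w) {
  d <- dim(img)
  was2d <- length(d) == 2
  if (was2d) dim(img) <- c(d, 1)
  minv <- matrix(c(dim(img)[2] / out_w, 0, 0,
                   0, dim(img)[1] / out_h, 0), 2, 3, byrow = TRUE)
  out <- nn_warp_affine(img, minv, 0, as.integer(out_h), as.integer(out_w),
                        clamp = TRUE)
  if (was2d) dim(out) <- c(out_h, out_w)
  out
}
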