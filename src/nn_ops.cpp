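// Minimal CNN primitives: stride-1 convolution via im2col + GEMM, 2x2 max
// pooling, nearest-neighbour upsampling, bilinear affine warp, and the
// flood fill used by the mask decoder. All tensors are R arrays in
// (H, W, C, N) layout (column-major, matching R's array semantics).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static void dims4(const NumericVector& x, int out[4]) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) out[i] = d[i];
}

// im2col for one image: x is H x W x C (pointer), output (k*k*C) x (Ho*Wo).
// Row order dh + k*dw + k*k*c matches R's column-major flattening of a
// (k, k, C, Cout) weight array.
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& cols) {
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  cols.zeros(k * k * C, (size_t)Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int r = dh + k * dw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + dw - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = xc + (size_t)wi * H;
          double* dst = cols.colptr((size_t)wo * Ho) + r;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + dh - pad;
            if (hi < 0 || hi >= H) continue;
            dst[(size_t)ho * cols.n_rows] = src[hi];
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& cols, int H, int W, int C, int k,
                       int pad, double* gx) {
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  for (int c = 0; c < C; ++c) {
    double* gxc = gx + (size_t)c * H * W;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int r = dh + k * dw + k * k * c;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo + dw - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = gxc + (size_t)wi * H;
          const double* src = cols.colptr((size_t)wo * Ho) + r;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho + dh - pad;
            if (hi < 0 || hi >= H) continue;
            dst[hi] += src[(size_t)ho * cols.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv_fw(NumericVector x, NumericVector w, NumericVector b,
                         int pad) {
  int dx[4], dw[4];
  dims4(x, dx); dims4(w, dw);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != C) stop("weight dims do not match input channels");
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  if (Ho <= 0 || Wo <= 0) stop("kernel larger than padded input");

  NumericVector y = alloc4(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(&w[0]), k * k * C, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(&b[0]), Cout, false, true);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(&x[(size_t)n * H * W * C], H, W, C, k, pad, cols);
    arma::mat ym(&y[(size_t)n * Ho * Wo * Cout], (size_t)Ho * Wo, Cout,
                 false, true);
    ym = cols.t() * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv_bw(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  int dx[4], dw[4], dg[4];
  dims4(x, dx); dims4(w, dw); dims4(gy, dg);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  const int Ho = dg[0], Wo = dg[1];

  NumericVector gx = alloc4(H, W, C, N);
  NumericVector gw = alloc4(k, k, C, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(const_cast<double*>(&w[0]), k * k * C, Cout, false, true);
  arma::mat gWm(&gw[0], k * k * C, Cout, false, true);
  arma::vec gbv(&gb[0], Cout, false, true);
  arma::mat cols;
  for (int n = 0; n < N; ++n) {
    im2col(&x[(size_t)n * H * W * C], H, W, C, k, pad, cols);
    arma::mat gym(const_cast<double*>(&gy[(size_t)n * Ho * Wo * Cout]),
                  (size_t)Ho * Wo, Cout, false, true);
    gWm += cols * gym;
    gbv += arma::sum(gym, 0).t();
    arma::mat gcols = Wm * gym.t();
    col2im_acc(gcols, H, W, C, k, pad, &gx[(size_t)n * H * W * C]);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List nn_maxpool_fw(NumericVector x) {
  int d[4];
  dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);  // 0-based index into x
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t i = base + (size_t)(2 * wo + dw) * H + 2 * ho + dh;
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          // y layout is (Ho, Wo, C, N): recompute target slot
          const size_t t = ((size_t)n * C + c) * Ho * Wo + (size_t)wo * Ho + ho;
          y[t] = best; idx[t] = (int)bi; ++q;
        }
    }
  (void)q;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bw(NumericVector gy, IntegerVector idx,
                            IntegerVector xdim) {
  NumericVector gx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector nn_upsample_fw(NumericVector x) {
  int d[4];
  dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y = alloc4(2 * H, 2 * W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bx = ((size_t)n * C + c) * H * W;
      const size_t by = ((size_t)n * C + c) * 4 * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = x[bx + (size_t)w * H + h];
          const size_t c0 = by + (size_t)(2 * w) * 2 * H + 2 * h;
          const size_t c1 = by + (size_t)(2 * w + 1) * 2 * H + 2 * h;
          y[c0] = v; y[c0 + 1] = v; y[c1] = v; y[c1 + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample_bw(NumericVector gy) {
  int d[4];
  dims4(gy, d);
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bx = ((size_t)n * C + c) * H * W;
      const size_t by = ((size_t)n * C + c) * (size_t)H2 * W2;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const size_t c0 = by + (size_t)(2 * w) * H2 + 2 * h;
          const size_t c1 = by + (size_t)(2 * w + 1) * H2 + 2 * h;
          gx[bx + (size_t)w * H + h] = gy[c0] + gy[c0 + 1] + gy[c1] + gy[c1 + 1];
        }
    }
  return gx;
}

// Bilinear affine warp of an H x W x C image. minv is the 2x3 inverse map
// taking output pixel-centre coordinates (x, y) = (j + 0.5, i + 0.5), 0-based,
// to source coordinates. Out-of-bounds samples take `fill`, or the nearest
// edge pixel when `clamp` is true (edge replication, used for resizing).
// [[Rcpp::export]]
NumericVector nn_warp_affine(NumericVector img, NumericMatrix minv,
                             double fill, int out_h, int out_w,
                             bool clamp = false) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("expected an H x W x C array");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out(Dimension(out_h, out_w, C));
  for (int j = 0; j < out_w; ++j) {
    const double x = j + 0.5;
    for (int i = 0; i < out_h; ++i) {
      const double y = i + 0.5;
      const double xs = minv(0, 0) * x + minv(0, 1) * y + minv(0, 2);
      const double ys = minv(1, 0) * x + minv(1, 1) * y + minv(1, 2);
      double u = xs - 0.5, v = ys - 0.5;
      if (clamp) {
        u = std::min(std::max(u, 0.0), (double)(W - 1));
        v = std::min(std::max(v, 0.0), (double)(H - 1));
      }
      const int j0 = (int)std::floor(u), i0 = (int)std::floor(v);
      const double fu = u - j0, fv = v - i0;
      for (int c = 0; c < C; ++c) {
        const double* p = &img[(size_t)c * H * W];
        double acc = 0.0;
        const double wts[4] = {(1 - fu) * (1 - fv), (1 - fu) * fv,
                               fu * (1 - fv), fu * fv};
        const int jj[4] = {j0, j0, j0 + 1, j0 + 1};
        const int ii[4] = {i0, i0 + 1, i0, i0 + 1};
        for (int t = 0; t < 4; ++t) {
          const double val = (ii[t] >= 0 && ii[t] < H && jj[t] >= 0 && jj[t] < W)
                                 ? p[(size_t)jj[t] * H + ii[t]]
                                 : fill;
          acc += wts[t] * val;
        }
        out[((size_t)c * out_w + j) * out_h + i] = acc;
      }
    }
  }
  return out;
}

// Bounding box (1-based [imin, imax, jmin, jmax]) of the connected component
// of `mask` (H x W logical) containing seed (pi, pj), 1-based; connectivity
// 4 or 8.
// [[Rcpp::export]]
IntegerVector nn_peak_component_box(LogicalMatrix mask, int pi, int pj,
                                    int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (pi < 1 || pi > H || pj < 1 || pj > W) stop("seed outside mask");
  if (!mask(pi - 1, pj - 1)) stop("seed pixel is not above threshold");
  std::vector<char> seen((size_t)H * W, 0);
  std::vector<int> stack;
  stack.push_back((pj - 1) * H + (pi - 1));
  seen[stack[0]] = 1;
  int imin = pi - 1, imax = pi - 1, jmin = pj - 1, jmax = pj - 1;
  const int n_nb = (connectivity == 8) ? 8 : 4;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!stack.empty()) {
    const int cur = stack.back();
    stack.pop_back();
    const int ci = cur % H, cj = cur / H;
    if (ci < imin) imin = ci;
    if (ci > imax) imax = ci;
    if (cj < jmin) jmin = cj;
    if (cj > jmax) jmax = cj;
    for (int t = 0; t < n_nb; ++t) {
      const int ni = ci + di[t], nj = cj + dj[t];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      const int q = nj * H + ni;
      if (!seen[q] && mask(ni, nj)) {
        seen[q] = 1;
        stack.push_back(q);
      }
    }
  }
  return IntegerVector::create(imin + 1, imax + 1, jmin + 1, jmax + 1);
}
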