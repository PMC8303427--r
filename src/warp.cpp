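#include <Rcpp.h>
using namespace Rcpp;

// Bilinear affine resampling of image batches.
//
// Layout: x is an H x W x C x N array (row index fastest, R column-major).
// theta is N x 6, one row (a, b, tx, c, d, ty) per image, acting on
// normalized coordinates u (width) and v (height) in [-1, 1]:
//   us = a*u + b*v + tx,  vs = c*u + d*v + ty
// The output pixel at (u, v) samples the input at (us, vs); samples falling
// outside the image are zero.

static inline double pix(const double* x, int H, int W, int y, int xx,
                         std::size_t chan_off) {
  if (y < 0 || y >= H || xx < 0 || xx >= W) return 0.0;
  return x[chan_off + (std::size_t)y + (std::size_t)xx * H];
}

// [[Rcpp::export]]
NumericVector cpp_affine_warp(NumericVector x, NumericMatrix theta) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out(x.size());
  out.attr("dim") = d;
  const double* px = x.begin();
  double* po = out.begin();
  const std::size_t img = (std::size_t)H * W * C;
  const double su = (W > 1) ? 2.0 / (W - 1) : 0.0;
  const double sv = (H > 1) ? 2.0 / (H - 1) : 0.0;
  for (int n = 0; n < N; ++n) {
    const double a = theta(n, 0), b = theta(n, 1), tx = theta(n, 2);
    const double c = theta(n, 3), dd = theta(n, 4), ty = theta(n, 5);
    const std::size_t noff = (std::size_t)n * img;
    for (int j = 0; j < W; ++j) {
      const double u = su * j - ((W > 1) ? 1.0 : 0.0);
      for (int i = 0; i < H; ++i) {
        const double v = sv * i - ((H > 1) ? 1.0 : 0.0);
        const double us = a * u + b * v + tx;
        const double vs = c * u + dd * v + ty;
        const double col = (us + 1.0) * 0.5 * (W - 1);
        const double row = (vs + 1.0) * 0.5 * (H - 1);
        const int x0 = (int)std::floor(col), y0 = (int)std::floor(row);
        const double fx = col - x0, fy = row - y0;
        for (int ch = 0; ch < C; ++ch) {
          const std::size_t co = noff + (std::size_t)ch * H * W;
          const double i00 = pix(px, H, W, y0, x0, co);
          const double i01 = pix(px, H, W, y0, x0 + 1, co);
          const double i10 = pix(px, H, W, y0 + 1, x0, co);
          const double i11 = pix(px, H, W, y0 + 1, x0 + 1, co);
          po[co + (std::size_t)i + (std::size_t)j * H] =
            (1 - fy) * ((1 - fx) * i00 + fx * i01) +
            fy * ((1 - fx) * i10 + fx * i11);
        }
      }
    }
  }
  return out;
}

// Gradient of the warp with respect to the six affine parameters.
// dY has the same layout as the warp output. Returns an N x 6 matrix.
// (The gradient with respect to the input image is never needed here:
// the warp sits directly on the network input.)
// [[Rcpp::export]]
NumericMatrix cpp_affine_warp_dtheta(NumericVector x, NumericMatrix theta,
                                     NumericVector dY) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericMatrix dth(N, 6);
  const double* px = x.begin();
  const double* pg = dY.begin();
  const std::size_t img = (std::size_t)H * W * C;
  const double su = (W > 1) ? 2.0 / (W - 1) : 0.0;
  const double sv = (H > 1) ? 2.0 / (H - 1) : 0.0;
  const double dcol_dus = 0.5 * (W - 1);
  const double drow_dvs = 0.5 * (H - 1);
  for (int n = 0; n < N; ++n) {
    const double a = theta(n, 0), b = theta(n, 1), tx = theta(n, 2);
    const double c = theta(n, 3), dd = theta(n, 4), ty = theta(n, 5);
    const std::size_t noff = (std::size_t)n * img;
    double g[6] = {0, 0, 0, 0, 0, 0};
    for (int j = 0; j < W; ++j) {
      const double u = su * j - ((W > 1) ? 1.0 : 0.0);
      for (int i = 0; i < H; ++i) {
        const double v = sv * i - ((H > 1) ? 1.0 : 0.0);
        const double us = a * u + b * v + tx;
        const double vs = c * u + dd * v + ty;
        const double col = (us + 1.0) * dcol_dus;
        const double row = (vs + 1.0) * drow_dvs;
        const int x0 = (int)std::floor(col), y0 = (int)std::floor(row);
        const double fx = col - x0, fy = row - y0;
        double dfx = 0.0, dfy = 0.0;
        for (int ch = 0; ch < C; ++ch) {
          const std::size_t co = noff + (std::size_t)ch * H * W;
          const double i00 = pix(px, H, W, y0, x0, co);
          const double i01 = pix(px, H, W, y0, x0 + 1, co);
          const double i10 = pix(px, H, W, y0 + 1, x0, co);
          const double i11 = pix(px, H, W, y0 + 1, x0 + 1, co);
          const double gy = pg[co + (std::size_t)i + (std::size_t)j * H];
          dfx += gy * ((1 - fy) * (i01 - i00) + fy * (i11 - i10));
          dfy += gy * ((1 - fx) * (i10 - i00) + fx * (i11 - i01));
        }
        const double dus = dfx * dcol_dus;
        const double dvs = dfy * drow_dvs;
        g[0] += dus * u; g[1] += dus * v; g[2] += dus;
        g[3] += dvs * u; g[4] += dvs * v; g[5] += dvs;
      }
    }
    for (int k = 0; k < 6; ++k) dth(n, k) = g[k];
  }
  return dth;
}

// Fused pool(warp(x)): average-pools the warped image over s x s blocks
// without materializing the full-resolution warp. Identical arithmetic to
// cpp_affine_warp followed by block mean.
// [[Rcpp::export]]
NumericVector cpp_warp_pool(NumericVector x, NumericMatrix theta, int s) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = H / s, W2 = W / s;
  NumericVector out((std::size_t)H2 * W2 * C * N);
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* px = x.begin();
  double* po = out.begin();
  const std::size_t img = (std::size_t)H * W * C;
  const std::size_t img2 = (std::size_t)H2 * W2 * C;
  const double su = (W > 1) ? 2.0 / (W - 1) : 0.0;
  const double sv = (H > 1) ? 2.0 / (H - 1) : 0.0;
  const double inv = 1.0 / (s * s);
  for (int n = 0; n < N; ++n) {
    const double a = theta(n, 0), b = theta(n, 1), tx = theta(n, 2);
    const double c = theta(n, 3), dd = theta(n, 4), ty = theta(n, 5);
    const std::size_t noff = (std::size_t)n * img;
    const std::size_t noff2 = (std::size_t)n * img2;
    for (int j = 0; j < W; ++j) {
      const double u = su * j - ((W > 1) ? 1.0 : 0.0);
      const int j2 = j / s;
      for (int i = 0; i < H; ++i) {
        const double v = sv * i - ((H > 1) ? 1.0 : 0.0);
        const int i2 = i / s;
        const double us = a * u + b * v + tx;
        const double vs = c * u + dd * v + ty;
        const double col = (us + 1.0) * 0.5 * (W - 1);
        const double row = (vs + 1.0) * 0.5 * (H - 1);
        const int x0 = (int)std::floor(col), y0 = (int)std::floor(row);
        const double fx = col - x0, fy = row - y0;
        for (int ch = 0; ch < C; ++ch) {
          const std::size_t co = noff + (std::size_t)ch * H * W;
          const double val =
            (1 - fy) * ((1 - fx) * pix(px, H, W, y0, x0, co) +
                        fx * pix(px, H, W, y0, x0 + 1, co)) +
            fy * ((1 - fx) * pix(px, H, W, y0 + 1, x0, co) +
                  fx * pix(px, H, W, y0 + 1, x0 + 1, co));
          po[noff2 + (std::size_t)ch * H2 * W2 + (std::size_t)i2 +
             (std::size_t)j2 * H2] += val * inv;
        }
      }
    }
  }
  return out;
}

// Gradient of sum(dYp * cpp_warp_pool(x, theta, s)) w.r.t. theta.
// [[Rcpp::export]]
NumericMatrix cpp_warp_pool_dtheta(NumericVector x, NumericMatrix theta,
                                   NumericVector dYp, int s) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = H / s, W2 = W / s;
  NumericMatrix dth(N, 6);
  const double* px = x.begin();
  const double* pg = dYp.begin();
  const std::size_t img = (std::size_t)H * W * C;
  const std::size_t img2 = (std::size_t)H2 * W2 * C;
  const double su = (W > 1) ? 2.0 / (W - 1) : 0.0;
  const double sv = (H > 1) ? 2.0 / (H - 1) : 0.0;
  const double dcol_dus = 0.5 * (W - 1);
  const double drow_dvs = 0.5 * (H - 1);
  const double inv = 1.0 / (s * s);
  for (int n = 0; n < N; ++n) {
    const double a = theta(n, 0), b = theta(n, 1), tx = theta(n, 2);
    const double c = theta(n, 3), dd = theta(n, 4), ty = theta(n, 5);
    const std::size_t noff = (std::size_t)n * img;
    const std::size_t noff2 = (std::size_t)n * img2;
    double g[6] = {0, 0, 0, 0, 0, 0};
    for (int j = 0; j < W; ++j) {
      const double u = su * j - ((W > 1) ? 1.0 : 0.0);
      const int j2 = j / s;
      for (int i = 0; i < H; ++i) {
        const double v = sv * i - ((H > 1) ? 1.0 : 0.0);
        const int i2 = i / s;
        const double us = a * u + b * v + tx;
        const double vs = c * u + dd * v + ty;
        const double col = (us + 1.0) * dcol_dus;
        const double row = (vs + 1.0) * drow_dvs;
        const int x0 = (int)std::floor(col), y0 = (int)std::floor(row);
        const double fx = col - x0, fy = row - y0;
        double dfx = 0.0, dfy = 0.0;
        for (int ch = 0; ch < C; ++ch) {
          const std::size_t co = noff + (std::size_t)ch * H * W;
          const double i00 = pix(px, H, W, y0, x0, co);
          const double i01 = pix(px, H, W, y0, x0 + 1, co);
          const double i10 = pix(px, H, W, y0 + 1, x0, co);
          const double i11 = pix(px, H, W, y0 + 1, x0 + 1, co);
          const double gy = pg[noff2 + (std::size_t)ch * H2 * W2 +
                               (std::size_t)i2 + (std::size_t)j2 * H2] * inv;
          dfx += gy * ((1 - fy) * (i01 - i00) + fy * (i11 - i10));
          dfy += gy * ((1 - fx) * (i10 - i00) + fx * (i11 - i01));
        }
        const double dus = dfx * dcol_dus;
        const double dvs = dfy * drow_dvs;
        g[0] += dus * u; g[1] += dus * v; g[2] += dus;
        g[3] += dvs * u; g[4] += dvs * v; g[5] += dvs;
      }
    }
    for (int k = 0; k < 6; ++k) dth(n, k) = g[k];
  }
  return dth;
}

// out[idx[k]] += val[k], 1-based indices; col2im accumulation for the
// convolution backward pass.
// [[Rcpp::export]]
NumericVector cpp_scatter_add(NumericVector val, IntegerVector idx, int n) {
  NumericVector out(n);
  double* po = out.begin();
  const double* pv = val.begin();
  const int* pi = idx.begin();
  const R_xlen_t m = val.size();
  for (R_xlen_t k = 0; k < m; ++k) po[pi[k] - 1] += pv[k];
  return out;
}
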