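// Low-level numerical kernels for the compressed U-Net engine and the
// postprocessing stage. Activations are stored as (H*W) x C matrices with the
// spatial index p = col*H + row (column-major image layout, matching R).
// Convolutions use single precision internally (BLAS sgemm); the R interface
// stays double.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::fmat to_fmat(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  const double* src = x.begin();
  float* dst = out.memptr();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static NumericMatrix to_rmat(const arma::fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  const float* src = x.memptr();
  double* dst = out.begin();
  const size_t n = (size_t)x.n_rows * x.n_cols;
  for (size_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

// Gather the f x f zero-padded neighborhood of every pixel.
// Patch column index q = ch*f*f + ky*f + kx; output pixel (r,c) reads input
// pixel (r + ky - pad, c + kx - pad).
static void build_im2col(const arma::fmat& X, int H, int W, int f, arma::fmat& P) {
  const int C = X.n_cols, pad = f / 2;
  P.zeros((size_t)H * W, (size_t)f * f * C);
  for (int ch = 0; ch < C; ++ch) {
    const float* xcol = X.colptr(ch);
    for (int ky = 0; ky < f; ++ky) {
      for (int kx = 0; kx < f; ++kx) {
        const int q = ch * f * f + ky * f + kx;
        const int dy = ky - pad, dx = kx - pad;
        float* pcol = P.colptr(q);
        const int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        for (int c = 0; c < W; ++c) {
          const int sc = c + dx;
          if (sc < 0 || sc >= W) continue;
          const float* src = xcol + (size_t)sc * H + dy;
          float* dst = pcol + (size_t)c * H;
          for (int r = r0; r < r1; ++r) dst[r] = src[r];
        }
      }
    }
  }
}

// Scatter-add transpose of build_im2col.
static void scatter_col2im(const arma::fmat& dP, int H, int W, int f, int C,
                           arma::fmat& dX) {
  const int pad = f / 2;
  dX.zeros((size_t)H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    float* xcol = dX.colptr(ch);
    for (int ky = 0; ky < f; ++ky) {
      for (int kx = 0; kx < f; ++kx) {
        const int q = ch * f * f + ky * f + kx;
        const int dy = ky - pad, dx = kx - pad;
        const float* pcol = dP.colptr(q);
        const int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        for (int c = 0; c < W; ++c) {
          const int sc = c + dx;
          if (sc < 0 || sc >= W) continue;
          float* dst = xcol + (size_t)sc * H + dy;
          const float* src = pcol + (size_t)c * H;
          for (int r = r0; r < r1; ++r) dst[r] += src[r];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_fwd(const NumericMatrix& Xr, int H, int W, int f,
                           const NumericMatrix& Wr, const NumericVector& br) {
  arma::fmat X = to_fmat(Xr);
  arma::fmat Wm = to_fmat(Wr);
  arma::fmat P;
  build_im2col(X, H, W, f, P);
  arma::fmat Y = P * Wm;
  for (arma::uword j = 0; j < Y.n_cols; ++j) Y.col(j) += (float)br[j];
  return to_rmat(Y);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const NumericMatrix& Xr, const NumericMatrix& dYr,
                  int H, int W, int f, const NumericMatrix& Wr) {
  arma::fmat X = to_fmat(Xr);
  arma::fmat dY = to_fmat(dYr);
  arma::fmat Wm = to_fmat(Wr);
  arma::fmat P;
  build_im2col(X, H, W, f, P);
  arma::fmat dW = P.t() * dY;
  arma::fmat db = arma::sum(dY, 0).t();
  arma::fmat dP = dY * Wm.t();
  arma::fmat dX;
  scatter_col2im(dP, H, W, f, X.n_cols, dX);
  return List::create(_["dX"] = to_rmat(dX), _["dW"] = to_rmat(dW),
                      _["db"] = to_rmat(db));
}

// 2x2 max pooling, stride 2. Returns pooled activations and the (1-based)
// source row index of each maximum for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericMatrix& Xr, int H, int W) {
  const int C = Xr.ncol(), Ho = H / 2, Wo = W / 2;
  NumericMatrix Y((size_t)Ho * Wo, C);
  IntegerMatrix idx((size_t)Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int p00 = (2 * c) * H + 2 * r;
        const int cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
        int best = cand[0];
        double bv = Xr(cand[0], ch);
        for (int k = 1; k < 4; ++k) {
          const double v = Xr(cand[k], ch);
          if (v > bv) { bv = v; best = cand[k]; }
        }
        const int po = c * Ho + r;
        Y(po, ch) = bv;
        idx(po, ch) = best + 1;
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dYr, const IntegerMatrix& idx,
                              int HW) {
  const int C = dYr.ncol();
  NumericMatrix dX(HW, C);
  for (int ch = 0; ch < C; ++ch)
    for (int i = 0; i < dYr.nrow(); ++i)
      dX(idx(i, ch) - 1, ch) += dYr(i, ch);
  return dX;
}

// Connected components of a binary mask (8-connectivity), BFS labelling.
// Returns integer labels (0 where mask == 0) and component sizes.
// [[Rcpp::export]]
List cpp_label_components(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> sizes;
  std::queue<std::pair<int, int> > q;
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      int sz = 0;
      lab(r0, c0) = next;
      q.push(std::make_pair(r0, c0));
      while (!q.empty()) {
        const int r = q.front().first, c = q.front().second;
        q.pop();
        ++sz;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
      sizes.push_back(sz);
    }
  }
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes));
}

// Bilinear resize with pixel-center alignment and edge clamping.
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& img, int outH, int outW) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(outH, outW);
  const double sy = (double)H / outH, sx = (double)W / outW;
  for (int c = 0; c < outW; ++c) {
    double x = (c + 0.5) * sx - 0.5;
    if (x < 0) x = 0;
    if (x > W - 1) x = W - 1;
    const int x0 = (int)std::floor(x), x1 = std::min(x0 + 1, W - 1);
    const double wx = x - x0;
    for (int r = 0; r < outH; ++r) {
      double y = (r + 0.5) * sy - 0.5;
      if (y < 0) y = 0;
      if (y > H - 1) y = H - 1;
      const int y0 = (int)std::floor(y), y1 = std::min(y0 + 1, H - 1);
      const double wy = y - y0;
      out(r, c) = (1 - wy) * ((1 - wx) * img(y0, x0) + wx * img(y0, x1)) +
                  wy * ((1 - wx) * img(y1, x0) + wx * img(y1, x1));
    }
  }
  return out;
}
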