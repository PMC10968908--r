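#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as (H*W) x C matrices, pixels column-major in (row, col)
// order, i.e. pixel (i, j) of channel c sits at matrix row i + j*H (0-based).
// Convolutions are "same"-padded with zeros; `k` is the (odd) kernel size.

// Lay out sliding-window patches so that a k*k conv becomes a single gemm:
// out = im2col(x) %*% Wmat, with Wmat of shape (k*k*C) x Cout whose rows are
// ordered offset-major ((t - 1)*C + c for offset t and input channel c).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& x, int H, int W, int k) {
  const int C = x.ncol();
  const int half = k / 2;
  const int HW = H * W;
  NumericMatrix col(HW, k * k * C);
  const double* xp = x.begin();
  double* cp = col.begin();
  int t = 0;
  for (int dx = -half; dx <= half; ++dx) {
    for (int dy = -half; dy <= half; ++dy, ++t) {
      for (int c = 0; c < C; ++c) {
        double* dst = cp + (size_t)(t * C + c) * HW;
        const double* src = xp + (size_t)c * HW;
        for (int j = 0; j < W; ++j) {
          int sj = j + dx;
          double* d = dst + (size_t)j * H;
          if (sj < 0 || sj >= W) {
            for (int i = 0; i < H; ++i) d[i] = 0.0;
            continue;
          }
          const double* s = src + (size_t)sj * H;
          int lo = std::max(0, -dy), hi = std::min(H, H - dy);
          for (int i = 0; i < lo; ++i) d[i] = 0.0;
          for (int i = lo; i < hi; ++i) d[i] = s[i + dy];
          for (int i = hi; i < H; ++i) d[i] = 0.0;
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col: scatter-add patch-gradient columns back onto the image
// grid. `gcol` is (H*W) x (k*k*C); returns (H*W) x C.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& gcol, int H, int W, int k) {
  const int half = k / 2;
  const int HW = H * W;
  const int C = gcol.ncol() / (k * k);
  NumericMatrix gx(HW, C);
  const double* gp = gcol.begin();
  double* xp = gx.begin();
  int t = 0;
  for (int dx = -half; dx <= half; ++dx) {
    for (int dy = -half; dy <= half; ++dy, ++t) {
      for (int c = 0; c < C; ++c) {
        const double* src = gp + (size_t)(t * C + c) * HW;
        double* dst = xp + (size_t)c * HW;
        for (int j = 0; j < W; ++j) {
          int sj = j + dx;
          if (sj < 0 || sj >= W) continue;
          const double* s = src + (size_t)j * H;
          double* d = dst + (size_t)sj * H;
          int lo = std::max(0, -dy), hi = std::min(H, H - dy);
          for (int i = lo; i < hi; ++i) d[i + dy] += s[i];
        }
      }
    }
  }
  return gx;
}
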