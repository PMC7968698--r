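// Performance kernels for the convolution engine: patch extraction
// (im2col) and its scatter-add inverse (col2im). Tensors are R arrays
// dim c(H, W, N, C), column-major; patch matrices are (k*k*C) x
// (OH*OW*N) with rows ordered (dh, dw, c) and columns (oh, ow, n).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims, int k,
                         int stride) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int OH = (H - k) / stride + 1, OW = (W - k) / stride + 1;
  NumericMatrix out(k * k * C, OH * OW * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;          // one image-channel plane
  const R_xlen_t chan = plane * N;                 // stride between channels
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double* o = op + (R_xlen_t)(oh + OH * (ow + (R_xlen_t)OW * n)) *
                          (k * k * C);
        const double* base = xp + (R_xlen_t)n * plane;
        for (int c = 0; c < C; ++c) {
          const double* pc = base + (R_xlen_t)c * chan;
          for (int dw = 0; dw < k; ++dw) {
            const double* col = pc + (R_xlen_t)(ow * stride + dw) * H +
                                oh * stride;
            for (int dh = 0; dh < k; ++dh) *o++ = col[dh];
          }
        }
      }
    }
  }
  return out;
}

// cols: (k*k*C) x (OH*OW*N) gradient patches; returns the (padded) input
// gradient array dim c(H, W, N, C) by scatter-add.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, IntegerVector dims, int k,
                         int stride) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int OH = (H - k) / stride + 1, OW = (W - k) / stride + 1;
  NumericVector out((R_xlen_t)H * W * N * C);
  const double* cp = cols.begin();
  double* op = out.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t chan = plane * N;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* src = cp + (R_xlen_t)(oh + OH * (ow + (R_xlen_t)OW * n)) *
                                 (k * k * C);
        double* base = op + (R_xlen_t)n * plane;
        for (int c = 0; c < C; ++c) {
          double* pc = base + (R_xlen_t)c * chan;
          for (int dw = 0; dw < k; ++dw) {
            double* col = pc + (R_xlen_t)(ow * stride + dw) * H + oh * stride;
            for (int dh = 0; dh < k; ++dh) col[dh] += *src++;
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
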