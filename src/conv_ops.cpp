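#include <Rcpp.h>
using namespace Rcpp;

// Unrolls one (H, W, C) image into a (KH*KW*C) x (Ho*Wo) matrix so that
// convolution becomes a single GEMM. Row index runs kh fastest, then kw,
// then channel, matching kernel arrays stored as (KH, KW, Cin, Cout).
// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo);
  const double *px = x.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      double *pc = &out(0, col);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double *xc = px + (size_t)c * H * W;
        for (int j = 0; j < kw; ++j) {
          const int wj = w0 + j;
          const bool win = wj >= 0 && wj < W;
          for (int i = 0; i < kh; ++i) {
            const int hi = h0 + i;
            double v = 0.0;
            if (win && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wj];
            pc[i + kh * (j + kw * c)] = v;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: folds a column matrix back into an (H, W, C)
// image, accumulating overlapping contributions.
// [[Rcpp::export(name = ".col2im_cpp")]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector out((size_t)H * W * C);
  double *px = out.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      const double *pc = &cols(0, col);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double *xc = px + (size_t)c * H * W;
        for (int j = 0; j < kw; ++j) {
          const int wj = w0 + j;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int hi = h0 + i;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wj] += pc[i + kh * (j + kw * c)];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}
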