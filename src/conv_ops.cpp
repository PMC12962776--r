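// Convolutional forward-pass primitives for the hierarchical network.
// Single image, stride 1, "same" zero padding; im2col + GEMM in single
// precision keeps a 224x224 forward pass tractable on one CPU core.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// x: H x W x Cin array; w: (k*k*Cin) x Cout matrix with patch elements
// ordered (dy, dx, channel); returns H x W x Cout array.
// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2dForward(NumericVector x, NumericMatrix w,
                            NumericVector bias, int k) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2];
  const int pad = (k - 1) / 2;
  const int kk = k * k, patch = kk * C;
  const int Cout = w.ncol();
  if (w.nrow() != patch) stop("weight rows do not match k*k*Cin");

  arma::fmat wf(patch, Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < patch; ++i) wf(i, j) = (float)w(i, j);

  arma::fmat col(patch, (size_t)H * W, arma::fill::zeros);
  const double *xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = xp + (size_t)c * H * W;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int row = dy + k * dx + kk * c;
        // output pixel (h, w) reads input (h + dy - pad, w + dx - pad)
        for (int ww = 0; ww < W; ++ww) {
          const int iw = ww + dx - pad;
          if (iw < 0 || iw >= W) continue;
          const double *src = plane + (size_t)iw * H;
          float *dst = col.colptr((size_t)ww * H);
          const int h0 = std::max(0, pad - dy);
          const int h1 = std::min(H, H + pad - dy);
          for (int hh = h0; hh < h1; ++hh)
            dst[(size_t)hh * patch + row] = (float)src[hh + dy - pad];
        }
      }
    }
  }

  arma::fmat out = wf.t() * col;  // Cout x (H*W)
  NumericVector res((size_t)H * W * Cout);
  res.attr("dim") = IntegerVector::create(H, W, Cout);
  double *rp = res.begin();
  for (int co = 0; co < Cout; ++co) {
    const float b = (float)bias[co];
    for (size_t p = 0; p < (size_t)H * W; ++p)
      rp[(size_t)co * H * W + p] = (double)(out(co, p) + b);
  }
  return res;
}

// 2x2 max pooling with stride 2 on an H x W x C array (H, W even).
// [[Rcpp::export(name = ".maxPool2x2")]]
NumericVector maxPool2x2(NumericVector x) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector res((size_t)Ho * Wo * C);
  res.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double *xp = x.begin();
  double *rp = res.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = xp + (size_t)c * H * W;
    double *oplane = rp + (size_t)c * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double *c0 = plane + (size_t)(2 * wo) * H;
      const double *c1 = plane + (size_t)(2 * wo + 1) * H;
      for (int ho = 0; ho < Ho; ++ho) {
        const double a = std::max(c0[2 * ho], c0[2 * ho + 1]);
        const double b = std::max(c1[2 * ho], c1[2 * ho + 1]);
        oplane[(size_t)wo * Ho + ho] = std::max(a, b);
      }
    }
  }
  return res;
}
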