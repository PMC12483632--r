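#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout throughout: (h, w, batch, channel), column-major, so the
// h axis is contiguous. im2col rows run over (h, w, batch); columns over
// (kernel offset major, input channel minor). Stride-1 'same' padding.

// [[Rcpp::export(name = ".cppIm2col")]]
NumericMatrix cppIm2col(const NumericVector& x, int h, int w, int n,
                        int cin, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t R = (R_xlen_t)h * w * n;
  NumericMatrix M(R, (R_xlen_t)k * k * cin);
  const double* xp = x.begin();
  double* mp = M.begin();
  for (int dy = 0; dy < k; ++dy) {
    for (int dx = 0; dx < k; ++dx) {
      const int o = dy * k + dx;
      for (int c = 0; c < cin; ++c) {
        double* col = mp + ((R_xlen_t)o * cin + c) * R;
        for (int s = 0; s < n; ++s) {
          for (int j = 0; j < w; ++j) {
            const int sj = j + dx - p; // source column
            double* dst = col + ((R_xlen_t)s * w + j) * h;
            if (sj < 0 || sj >= w) {
              std::fill(dst, dst + h, 0.0);
              continue;
            }
            const double* src =
              xp + (((R_xlen_t)c * n + s) * w + sj) * h;
            const int lo = std::max(0, p - dy);      // first valid out row
            const int hi = std::min(h, h + p - dy);  // one past last
            if (lo > 0) std::fill(dst, dst + lo, 0.0);
            if (hi < h) std::fill(dst + hi, dst + h, 0.0);
            // out row i reads source row i + dy - p
            std::copy(src + lo + dy - p, src + hi + dy - p, dst + lo);
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".cppCol2im")]]
NumericVector cppCol2im(const NumericMatrix& dM, int h, int w, int n,
                        int cin, int k) {
  const int p = (k - 1) / 2;
  const R_xlen_t R = (R_xlen_t)h * w * n;
  NumericVector dx((R_xlen_t)h * w * n * cin);
  const double* mp = dM.begin();
  double* xp = dx.begin();
  for (int dy = 0; dy < k; ++dy) {
    for (int dx_ = 0; dx_ < k; ++dx_) {
      const int o = dy * k + dx_;
      for (int c = 0; c < cin; ++c) {
        const double* col = mp + ((R_xlen_t)o * cin + c) * R;
        for (int s = 0; s < n; ++s) {
          for (int j = 0; j < w; ++j) {
            const int sj = j + dx_ - p;
            if (sj < 0 || sj >= w) continue;
            const double* src = col + ((R_xlen_t)s * w + j) * h;
            double* dst = xp + (((R_xlen_t)c * n + s) * w + sj) * h;
            const int lo = std::max(0, p - dy);
            const int hi = std::min(h, h + p - dy);
            for (int i = lo; i < hi; ++i) {
              dst[i + dy - p] += src[i];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(h, w, n, cin);
  return dx;
}

// 2x2 max pooling with stride 2 on an (h, w, n, c) tensor.
// [[Rcpp::export(name = ".cppMaxPool2")]]
NumericVector cppMaxPool2(const NumericVector& x, int h, int w, int n,
                          int c) {
  const int h2 = h / 2, w2 = w / 2;
  NumericVector y((R_xlen_t)h2 * w2 * n * c);
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t planes = (R_xlen_t)n * c;
  for (R_xlen_t pl = 0; pl < planes; ++pl) {
    const double* src = xp + pl * h * w;
    double* dst = yp + pl * h2 * w2;
    for (int j = 0; j < w2; ++j) {
      const double* c0 = src + (R_xlen_t)(2 * j) * h;
      const double* c1 = c0 + h;
      double* out = dst + (R_xlen_t)j * h2;
      for (int i = 0; i < h2; ++i) {
        const int r = 2 * i;
        double m = c0[r];
        if (c0[r + 1] > m) m = c0[r + 1];
        if (c1[r] > m) m = c1[r];
        if (c1[r + 1] > m) m = c1[r + 1];
        out[i] = m;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(h2, w2, n, c);
  return y;
}
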