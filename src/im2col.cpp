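#include <Rcpp.h>
using namespace Rcpp;

// Column extraction / scatter for 2-D convolution on a single H x W x C
// array (R column-major). Output positions are enumerated column-major
// (row fastest) so matrices reshape directly into R arrays.
//
// im2col: returns a (kh*kw*C) x (Ho*Wo) matrix. Row index runs kh fastest,
// then kw, then channel, matching the weight layout used in R.
// Padding is implicit zeros; reflection padding is applied as an explicit
// layer in R before calling with pad = 0.

// [[Rcpp::export(name = ".c_im2col")]]
NumericMatrix c_im2col(NumericVector x, int H, int W, int C,
                       int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo);
  const double *px = x.begin();
  double *po = out.begin();
  const int collen = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int n = wo * Ho + ho;
      double *dst = po + (size_t)n * collen;
      const int r0 = ho * sh - ph;
      const int c0 = wo * sw - pw;
      for (int c = 0; c < C; ++c) {
        const double *plane = px + (size_t)c * H * W;
        for (int j = 0; j < kw; ++j) {
          const int cc = c0 + j;
          const bool cok = (cc >= 0 && cc < W);
          for (int i = 0; i < kh; ++i) {
            const int rr = r0 + i;
            double v = 0.0;
            if (cok && rr >= 0 && rr < H) v = plane[(size_t)cc * H + rr];
            dst[c * kh * kw + j * kh + i] = v;
          }
        }
      }
    }
  }
  return out;
}

// col2im: adjoint of im2col; scatter-adds columns back into an H x W x C
// array. Used for conv backward-data and transpose-conv forward.

// [[Rcpp::export(name = ".c_col2im")]]
NumericVector c_col2im(NumericMatrix cols, int H, int W, int C,
                       int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  NumericVector x((size_t)H * W * C);
  double *px = x.begin();
  const double *po = cols.begin();
  const int collen = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int n = wo * Ho + ho;
      const double *src = po + (size_t)n * collen;
      const int r0 = ho * sh - ph;
      const int c0 = wo * sw - pw;
      for (int c = 0; c < C; ++c) {
        double *plane = px + (size_t)c * H * W;
        for (int j = 0; j < kw; ++j) {
          const int cc = c0 + j;
          if (cc < 0 || cc >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int rr = r0 + i;
            if (rr < 0 || rr >= H) continue;
            plane[(size_t)cc * H + rr] += src[c * kh * kw + j * kh + i];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C);
  return x;
}
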