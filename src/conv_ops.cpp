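#include <Rcpp.h>
using namespace Rcpp;

// Layout convention throughout: a single image is a column-major (H, W, C)
// array (row index fastest).  im2col rows are ordered (ki, kj, c) so that an
// R weight array of dim (kh, kw, Cin, Cout) flattened column-major lines up
// with the rows; columns are ordered (oh, ow) matching the column-major
// flattening of the (outH, outW) output plane.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, double padval) {
  const int outH = (H + 2 * ph - kh) / sh + 1;
  const int outW = (W + 2 * pw - kw) / sw + 1;
  NumericMatrix cols(kh * kw * C, outH * outW);
  const double* xp = x.begin();
  double* cp = cols.begin();
  const int nrow = kh * kw * C;
  for (int ow = 0; ow < outW; ++ow) {
    const int j0 = ow * sw - pw;
    for (int oh = 0; oh < outH; ++oh) {
      const int i0 = oh * sh - ph;
      double* col = cp + (size_t)(ow * outH + oh) * nrow;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          const int j = j0 + kj;
          const bool jin = (j >= 0 && j < W);
          for (int ki = 0; ki < kh; ++ki) {
            const int i = i0 + ki;
            col[(c * kw + kj) * kh + ki] =
              (jin && i >= 0 && i < H) ? xc[(size_t)j * H + i] : padval;
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add inverse of im2col (padding positions are dropped).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int outH = (H + 2 * ph - kh) / sh + 1;
  const int outW = (W + 2 * pw - kw) / sw + 1;
  NumericVector x((size_t)H * W * C);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const int nrow = kh * kw * C;
  for (int ow = 0; ow < outW; ++ow) {
    const int j0 = ow * sw - pw;
    for (int oh = 0; oh < outH; ++oh) {
      const int i0 = oh * sh - ph;
      const double* col = cp + (size_t)(ow * outH + oh) * nrow;
      for (int c = 0; c < C; ++c) {
        double* xc = xp + (size_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          const int j = j0 + kj;
          if (j < 0 || j >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int i = i0 + ki;
            if (i < 0 || i >= H) continue;
            xc[(size_t)j * H + i] += col[(c * kw + kj) * kh + ki];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling over a full (H, W, C, N) array; returns pooled values and the
// 1-based linear argmax index into the input for the backward scatter.
// [[Rcpp::export]]
List maxpool2d_cpp(NumericVector x, int H, int W, int C, int N,
                   int k, int s, int p) {
  const int outH = (H + 2 * p - k) / s + 1;
  const int outW = (W + 2 * p - k) / s + 1;
  const size_t plane = (size_t)H * W;
  NumericVector out((size_t)outH * outW * C * N);
  IntegerVector amax((size_t)outH * outW * C * N);
  const double* xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((size_t)n * C + c) * plane;
      for (int ow = 0; ow < outW; ++ow) {
        const int j0 = ow * s - p;
        for (int oh = 0; oh < outH; ++oh) {
          const int i0 = oh * s - p;
          double best = R_NegInf;
          size_t bidx = 0;
          for (int kj = 0; kj < k; ++kj) {
            const int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int i = i0 + ki;
              if (i < 0 || i >= H) continue;
              const double v = xc[(size_t)j * H + i];
              if (v > best) { best = v; bidx = (size_t)j * H + i; }
            }
          }
          const size_t oidx = ((size_t)n * C + c) * outH * outW +
                              (size_t)ow * outH + oh;
          out[oidx] = best;
          amax[oidx] = (int)(((size_t)n * C + c) * plane + bidx) + 1;
          ++o;
        }
      }
    }
  }
  (void)o;
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bwd_cpp(NumericVector gout, IntegerVector argmax,
                                int insize) {
  NumericVector gx(insize);
  for (R_xlen_t t = 0; t < gout.size(); ++t) gx[argmax[t] - 1] += gout[t];
  return gx;
}
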