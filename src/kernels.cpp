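// Hot-loop kernels for the channel-first tensor engine.
//
// Activations are (C, spatial*N) matrices, columns spatial-fastest then
// batch. These kernels do the memory-bound steps (im2col gather, col2im
// scatter-add, 2x max pooling, fused batch-norm passes, ReLU); all matrix
// products stay in R on BLAS. Kernel offsets are ordered axis-1 fastest,
// matching expand.grid(rep(list(0:2), nd)) on the R side.

#include <Rcpp.h>
#include <vector>
#include <cstring>

#define RESTRICT __restrict__
using namespace Rcpp;

// Gather 3x3 (nd=2) or 3x3x3 (nd=3) windows, zero padding 1, stride 1:
// x (Cin, Sp*N) -> XB (K*Cin, Sp*N).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, const IntegerVector& sp,
                         const int N) {
  const int nd = sp.size();
  const int Cin = x.nrow();
  R_xlen_t Sp = 1;
  for (int a = 0; a < nd; ++a) Sp *= sp[a];
  const int K = (nd == 2) ? 9 : 27;
  NumericMatrix XB(Rf_allocMatrix(REALSXP, K * Cin, Sp * N));
  const double* RESTRICT px = x.begin();
  double* RESTRICT pb = XB.begin();
  const int H = sp[0], W = sp[1], D = (nd == 3) ? sp[2] : 1;
  const R_xlen_t rows = (R_xlen_t)K * Cin;
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base = (R_xlen_t)n * Sp;
    for (int d = 0; d < D; ++d)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const R_xlen_t ocol = base + ((R_xlen_t)d * W + w) * H + h;
          double* dst = pb + ocol * rows;
          int k = 0;
          const int zlo = (nd == 3) ? -1 : 0, zhi = (nd == 3) ? 1 : 0;
          for (int oz = zlo; oz <= zhi; ++oz)
            for (int ox = -1; ox <= 1; ++ox)
              for (int oy = -1; oy <= 1; ++oy, ++k) {
                const int hh = h + oy, ww = w + ox, dd = d + oz;
                double* RESTRICT t = dst + (R_xlen_t)k * Cin;
                if (hh < 0 || hh >= H || ww < 0 || ww >= W ||
                    dd < 0 || dd >= D) {
                  for (int c = 0; c < Cin; ++c) t[c] = 0.0;
                  continue;
                }
                const R_xlen_t icol = base + ((R_xlen_t)dd * W + ww) * H + hh;
                const double* RESTRICT sc = px + icol * Cin;
                for (int c = 0; c < Cin; ++c) t[c] = sc[c];
              }
        }
  }
  return XB;
}

// Transpose of cpp_im2col: scatter-add dXB (K*Cin, Sp*N) back onto the
// input grid -> dx (Cin, Sp*N).
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dXB, const IntegerVector& sp,
                         const int N, const int Cin) {
  const int nd = sp.size();
  R_xlen_t Sp = 1;
  for (int a = 0; a < nd; ++a) Sp *= sp[a];
  const int K = (nd == 2) ? 9 : 27;
  NumericMatrix dx(Cin, Sp * N);
  const double* RESTRICT pb = dXB.begin();
  double* RESTRICT px = dx.begin();
  const int H = sp[0], W = sp[1], D = (nd == 3) ? sp[2] : 1;
  const R_xlen_t rows = (R_xlen_t)K * Cin;
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base = (R_xlen_t)n * Sp;
    for (int d = 0; d < D; ++d)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const R_xlen_t ocol = base + ((R_xlen_t)d * W + w) * H + h;
          const double* src = pb + ocol * rows;
          int k = 0;
          const int zlo = (nd == 3) ? -1 : 0, zhi = (nd == 3) ? 1 : 0;
          for (int oz = zlo; oz <= zhi; ++oz)
            for (int ox = -1; ox <= 1; ++ox)
              for (int oy = -1; oy <= 1; ++oy, ++k) {
                const int hh = h + oy, ww = w + ox, dd = d + oz;
                if (hh < 0 || hh >= H || ww < 0 || ww >= W ||
                    dd < 0 || dd >= D) continue;
                const R_xlen_t icol = base + ((R_xlen_t)dd * W + ww) * H + hh;
                double* RESTRICT t = px + icol * Cin;
                const double* RESTRICT s = src + (R_xlen_t)k * Cin;
                for (int c = 0; c < Cin; ++c) t[c] += s[c];
              }
        }
  }
  return dx;
}

// 2x max pooling (floor semantics) over 2 or 3 spatial axes.
// Returns out (C, prod(osp)*N) and the winning offset index per cell
// (ties -> first offset in scan order).
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericMatrix& x, const IntegerVector& sp,
                     const int N) {
  const int nd = sp.size();
  const int C = x.nrow();
  const int H = sp[0], W = sp[1], D = (nd == 3) ? sp[2] : 1;
  const int Ho = H / 2, Wo = W / 2, Do = (nd == 3) ? sp[2] / 2 : 1;
  R_xlen_t Sp = (R_xlen_t)H * W * D;
  R_xlen_t Spo = (R_xlen_t)Ho * Wo * Do;
  const int K = (nd == 2) ? 4 : 8;
  NumericMatrix out(C, Spo * N);
  IntegerMatrix amax(C, Spo * N);
  const double* RESTRICT px = x.begin();
  double* RESTRICT po = out.begin();
  int* RESTRICT pa = amax.begin();
  for (int n = 0; n < N; ++n) {
    const R_xlen_t ibase = (R_xlen_t)n * Sp, obase = (R_xlen_t)n * Spo;
    for (int d = 0; d < Do; ++d)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const R_xlen_t ocol = obase + ((R_xlen_t)d * Wo + w) * Ho + h;
          double* dst = po + ocol * C;
          int* dsta = pa + ocol * C;
          int k = 0;
          const int zhi = (nd == 3) ? 1 : 0;
          for (int oz = 0; oz <= zhi; ++oz)
            for (int ox = 0; ox <= 1; ++ox)
              for (int oy = 0; oy <= 1; ++oy, ++k) {
                const R_xlen_t icol = ibase +
                  ((R_xlen_t)(2 * d + oz) * W + (2 * w + ox)) * H +
                  (2 * h + oy);
                const double* s = px + icol * C;
                if (k == 0) {
                  std::memcpy(dst, s, C * sizeof(double));
                  for (int c = 0; c < C; ++c) dsta[c] = 0;
                } else {
                  for (int c = 0; c < C; ++c)
                    if (s[c] > dst[c]) { dst[c] = s[c]; dsta[c] = k; }
                }
              }
        }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& G,
                              const IntegerMatrix& amax,
                              const IntegerVector& sp, const int N) {
  const int nd = sp.size();
  const int C = G.nrow();
  const int H = sp[0], W = sp[1], D = (nd == 3) ? sp[2] : 1;
  const int Ho = H / 2, Wo = W / 2, Do = (nd == 3) ? sp[2] / 2 : 1;
  R_xlen_t Sp = (R_xlen_t)H * W * D;
  R_xlen_t Spo = (R_xlen_t)Ho * Wo * Do;
  NumericMatrix dx(C, Sp * N);
  const double* RESTRICT pg = G.begin();
  const int* RESTRICT pa = amax.begin();
  double* RESTRICT px = dx.begin();
  for (int n = 0; n < N; ++n) {
    const R_xlen_t ibase = (R_xlen_t)n * Sp, obase = (R_xlen_t)n * Spo;
    for (int d = 0; d < Do; ++d)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const R_xlen_t ocol = obase + ((R_xlen_t)d * Wo + w) * Ho + h;
          const double* g = pg + ocol * C;
          const int* a = pa + ocol * C;
          for (int c = 0; c < C; ++c) {
            const int k = a[c];
            const int oy = k & 1, ox = (k >> 1) & 1, oz = (k >> 2) & 1;
            const R_xlen_t icol = ibase +
              ((R_xlen_t)(2 * d + oz) * W + (2 * w + ox)) * H +
              (2 * h + oy);
            px[icol * C + c] += g[c];
          }
        }
  }
  return dx;
}

// Fused batch-norm forward: returns xhat and gamma*xhat + beta in one pass.
// [[Rcpp::export]]
List cpp_bn_fwd(const NumericMatrix& x, const NumericVector& mu,
                const NumericVector& invstd, const NumericVector& gamma,
                const NumericVector& beta) {
  const int C = x.nrow();
  const R_xlen_t M = x.ncol();
  NumericMatrix xhat(C, M), out(C, M);
  const double* RESTRICT px = x.begin();
  double* RESTRICT ph = xhat.begin();
  double* RESTRICT po = out.begin();
  std::vector<double> lmu(mu.begin(), mu.end()),
    liv(invstd.begin(), invstd.end()), lg(gamma.begin(), gamma.end()),
    lb(beta.begin(), beta.end());
  for (R_xlen_t j = 0; j < M; ++j) {
    const R_xlen_t off = j * C;
    for (int c = 0; c < C; ++c) {
      const double v = (px[off + c] - lmu[c]) * liv[c];
      ph[off + c] = v;
      po[off + c] = lg[c] * v + lb[c];
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// Fused batch-norm backward (training statistics).
// [[Rcpp::export]]
List cpp_bn_bwd_train(const NumericMatrix& dout, const NumericMatrix& xhat,
                      const NumericVector& gamma,
                      const NumericVector& invstd) {
  const int C = dout.nrow();
  const R_xlen_t M = dout.ncol();
  const double* RESTRICT pd = dout.begin();
  const double* RESTRICT ph = xhat.begin();
  std::vector<double> dg(C, 0.0), db(C, 0.0);
  for (R_xlen_t j = 0; j < M; ++j) {
    const R_xlen_t off = j * C;
    for (int c = 0; c < C; ++c) {
      dg[c] += pd[off + c] * ph[off + c];
      db[c] += pd[off + c];
    }
  }
  NumericMatrix dx(C, M);
  double* RESTRICT px = dx.begin();
  std::vector<double> a(C), b2(C), s2(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] * invstd[c];
    b2[c] = db[c] * gamma[c] / M * invstd[c];
    s2[c] = dg[c] * gamma[c] / M * invstd[c];
  }
  for (R_xlen_t j = 0; j < M; ++j) {
    const R_xlen_t off = j * C;
    for (int c = 0; c < C; ++c)
      px[off + c] = pd[off + c] * a[c] - b2[c] - ph[off + c] * s2[c];
  }
  return List::create(_["dgamma"] = NumericVector(dg.begin(), dg.end()),
                      _["dbeta"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}

// One-pass per-channel mean and (biased) variance over columns.
// [[Rcpp::export]]
List cpp_row_meanvar(const NumericMatrix& x) {
  const int C = x.nrow();
  const R_xlen_t M = x.ncol();
  const double* RESTRICT px = x.begin();
  std::vector<double> mu(C, 0.0), s2(C, 0.0);
  for (R_xlen_t j = 0; j < M; ++j) {
    const R_xlen_t off = j * C;
    for (int c = 0; c < C; ++c) {
      mu[c] += px[off + c];
      s2[c] += px[off + c] * px[off + c];
    }
  }
  for (int c = 0; c < C; ++c) {
    mu[c] /= M;
    s2[c] = s2[c] / M - mu[c] * mu[c];
    if (s2[c] < 0) s2[c] = 0;
  }
  return List::create(_["mean"] = NumericVector(mu.begin(), mu.end()),
                      _["var"] = NumericVector(s2.begin(), s2.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_fwd(const NumericMatrix& x) {
  NumericMatrix out(x.nrow(), x.ncol());
  const double* RESTRICT px = x.begin();
  double* RESTRICT po = out.begin();
  const R_xlen_t L = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < L; ++i) po[i] = px[i] > 0 ? px[i] : 0;
  return out;
}

// Backward through ReLU using the forward *output* (out > 0 <=> pass).
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(const NumericMatrix& G, const NumericMatrix& out) {
  NumericMatrix dx(G.nrow(), G.ncol());
  const double* RESTRICT pg = G.begin();
  const double* RESTRICT po = out.begin();
  double* RESTRICT px = dx.begin();
  const R_xlen_t L = (R_xlen_t)G.nrow() * G.ncol();
  for (R_xlen_t i = 0; i < L; ++i) px[i] = po[i] > 0 ? pg[i] : 0;
  return dx;
}

// ---- direct convolution for a single input channel ------------------------
// First layers see Cin = 1 (one grey-level channel); building an im2col
// there would inflate the raw volume 9-27x. Direct accumulation instead.
// W: (1, Cout, K) array passed as a (Cout x K)-shaped view wk[k*Cout+co].

// [[Rcpp::export]]
NumericMatrix cpp_conv1_fwd(const NumericMatrix& x, const IntegerVector& sp,
                            const int N, const NumericVector& W,
                            const int Cout) {
  const int nd = sp.size();
  const int H = sp[0], Wd = sp[1], D = (nd == 3) ? sp[2] : 1;
  const R_xlen_t Sp = (R_xlen_t)H * Wd * D;
  const int K = (nd == 2) ? 9 : 27;
  NumericMatrix out(Rf_allocMatrix(REALSXP, Cout, Sp * N));
  const double* RESTRICT px = x.begin();
  double* RESTRICT po = out.begin();
  std::vector<double> w(W.begin(), W.end());   // (Cout, K) column-major
  std::vector<double> acc(Cout);
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base = (R_xlen_t)n * Sp;
    for (int d = 0; d < D; ++d)
      for (int ww = 0; ww < Wd; ++ww)
        for (int h = 0; h < H; ++h) {
          const R_xlen_t ocol = base + ((R_xlen_t)d * Wd + ww) * H + h;
          for (int c = 0; c < Cout; ++c) acc[c] = 0.0;
          int k = 0;
          const int zlo = (nd == 3) ? -1 : 0, zhi = (nd == 3) ? 1 : 0;
          for (int oz = zlo; oz <= zhi; ++oz)
            for (int ox = -1; ox <= 1; ++ox)
              for (int oy = -1; oy <= 1; ++oy, ++k) {
                const int hh = h + oy, wx = ww + ox, dd = d + oz;
                if (hh < 0 || hh >= H || wx < 0 || wx >= Wd ||
                    dd < 0 || dd >= D) continue;
                const double v =
                  px[base + ((R_xlen_t)dd * Wd + wx) * H + hh];
                const double* RESTRICT wr = w.data() + (R_xlen_t)k * Cout;
                for (int c = 0; c < Cout; ++c) acc[c] += wr[c] * v;
              }
          double* RESTRICT dst = po + ocol * Cout;
          for (int c = 0; c < Cout; ++c) dst[c] = acc[c];
        }
  }
  return out;
}

// Weight gradient of the Cin = 1 direct convolution: returns (Cout, K).
// [[Rcpp::export]]
NumericMatrix cpp_conv1_dw(const NumericMatrix& x, const NumericMatrix& G,
                           const IntegerVector& sp, const int N) {
  const int nd = sp.size();
  const int H = sp[0], Wd = sp[1], D = (nd == 3) ? sp[2] : 1;
  const R_xlen_t Sp = (R_xlen_t)H * Wd * D;
  const int K = (nd == 2) ? 9 : 27;
  const int Cout = G.nrow();
  const double* RESTRICT px = x.begin();
  const double* RESTRICT pg = G.begin();
  std::vector<double> dw((R_xlen_t)Cout * K, 0.0);
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base = (R_xlen_t)n * Sp;
    for (int d = 0; d < D; ++d)
      for (int ww = 0; ww < Wd; ++ww)
        for (int h = 0; h < H; ++h) {
          const R_xlen_t ocol = base + ((R_xlen_t)d * Wd + ww) * H + h;
          const double* RESTRICT g = pg + ocol * Cout;
          int k = 0;
          const int zlo = (nd == 3) ? -1 : 0, zhi = (nd == 3) ? 1 : 0;
          for (int oz = zlo; oz <= zhi; ++oz)
            for (int ox = -1; ox <= 1; ++ox)
              for (int oy = -1; oy <= 1; ++oy, ++k) {
                const int hh = h + oy, wx = ww + ox, dd = d + oz;
                if (hh < 0 || hh >= H || wx < 0 || wx >= Wd ||
                    dd < 0 || dd >= D) continue;
                const double v =
                  px[base + ((R_xlen_t)dd * Wd + wx) * H + hh];
                double* RESTRICT dwr = dw.data() + (R_xlen_t)k * Cout;
                for (int c = 0; c < Cout; ++c) dwr[c] += g[c] * v;
              }
        }
  }
  NumericMatrix out(Cout, K);
  std::copy(dw.begin(), dw.end(), out.begin());
  return out;
}

// Input gradient of the Cin = 1 direct convolution -> (1, Sp*N).
// [[Rcpp::export]]
NumericMatrix cpp_conv1_dx(const NumericMatrix& G, const IntegerVector& sp,
                           const int N, const NumericVector& W) {
  const int nd = sp.size();
  const int H = sp[0], Wd = sp[1], D = (nd == 3) ? sp[2] : 1;
  const R_xlen_t Sp = (R_xlen_t)H * Wd * D;
  const int K = (nd == 2) ? 9 : 27;
  const int Cout = G.nrow();
  NumericMatrix dx(1, Sp * N);
  const double* RESTRICT pg = G.begin();
  double* RESTRICT px = dx.begin();
  std::vector<double> w(W.begin(), W.end());
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base = (R_xlen_t)n * Sp;
    for (int d = 0; d < D; ++d)
      for (int ww = 0; ww < Wd; ++ww)
        for (int h = 0; h < H; ++h) {
          const R_xlen_t ocol = base + ((R_xlen_t)d * Wd + ww) * H + h;
          const double* RESTRICT g = pg + ocol * Cout;
          int k = 0;
          const int zlo = (nd == 3) ? -1 : 0, zhi = (nd == 3) ? 1 : 0;
          for (int oz = zlo; oz <= zhi; ++oz)
            for (int ox = -1; ox <= 1; ++ox)
              for (int oy = -1; oy <= 1; ++oy, ++k) {
                const int hh = h + oy, wx = ww + ox, dd = d + oz;
                if (hh < 0 || hh >= H || wx < 0 || wx >= Wd ||
                    dd < 0 || dd >= D) continue;
                const double* RESTRICT wr = w.data() + (R_xlen_t)k * Cout;
                double s = 0.0;
                for (int c = 0; c < Cout; ++c) s += wr[c] * g[c];
                px[base + ((R_xlen_t)dd * Wd + wx) * H + hh] += s;
              }
        }
  }
  return dx;
}
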