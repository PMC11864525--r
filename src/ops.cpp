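// Low-level volumetric operators backing the autograd engine.
//
// Array layouts (column-major, matching R):
//   activations x : (D1, D2, D3, C, N)   spatial-first, then channel, then sample
//   weights     w : (K1, K2, K3, Cin, Cout)
// Convolutions are realized as im2col + GEMM: for one sample the patch matrix
// Pt has one row per output voxel and one column per (kernel offset, input
// channel); the weight tensor is already laid out as the matching (R x Cout)
// matrix, so the forward pass is a single GEMM per sample and the output lands
// directly in (O1,O2,O3,Cout) layout.

#include <RcppArmadillo.h>
using namespace Rcpp;

template <typename T>
static void pad_volume(const double* x, int D1, int D2, int D3, int C,
                       int p1, int p2, int p3, arma::Col<T>& xp) {
  const int P1 = D1 + 2 * p1, P2 = D2 + 2 * p2, P3 = D3 + 2 * p3;
  xp.zeros(static_cast<arma::uword>(P1) * P2 * P3 * C);
  T* xpd = xp.memptr();
  for (int c = 0; c < C; ++c)
    for (int d3 = 0; d3 < D3; ++d3)
      for (int d2 = 0; d2 < D2; ++d2) {
        const double* src = x + (size_t)d2 * D1 + (size_t)d3 * D1 * D2 +
                            (size_t)c * D1 * D2 * D3;
        T* dst = xpd + (size_t)p1 + (size_t)(d2 + p2) * P1 +
                 (size_t)(d3 + p3) * P1 * P2 + (size_t)c * P1 * P2 * P3;
        for (int d1 = 0; d1 < D1; ++d1) dst[d1] = static_cast<T>(src[d1]);
      }
}

template <typename T>
static void im2col(const arma::Col<T>& xp, int P1, int P2, int P3, int C,
                   int K1, int K2, int K3, int s1, int s2, int s3,
                   int O1, int O2, int O3, arma::Mat<T>& Pt) {
  const arma::uword L = static_cast<arma::uword>(O1) * O2 * O3;
  const T* xpd = xp.memptr();
  Pt.set_size(L, static_cast<arma::uword>(K1) * K2 * K3 * C);
  arma::uword r = 0;
  for (int c = 0; c < C; ++c)
    for (int k3 = 0; k3 < K3; ++k3)
      for (int k2 = 0; k2 < K2; ++k2)
        for (int k1 = 0; k1 < K1; ++k1, ++r) {
          T* col = Pt.colptr(r);
          arma::uword l = 0;
          for (int o3 = 0; o3 < O3; ++o3)
            for (int o2 = 0; o2 < O2; ++o2) {
              const T* src = xpd + (size_t)k1 +
                             (size_t)(o2 * s2 + k2) * P1 +
                             (size_t)(o3 * s3 + k3) * P1 * P2 +
                             (size_t)c * P1 * P2 * P3;
              if (s1 == 1)
                for (int o1 = 0; o1 < O1; ++o1) col[l++] = src[o1];
              else
                for (int o1 = 0; o1 < O1; ++o1) col[l++] = src[o1 * s1];
            }
        }
}

static inline int out_dim(int D, int K, int s, int p) {
  const int span = D + 2 * p - K;
  return span < 0 ? 0 : span / s + 1;
}

template <typename T>
static NumericVector conv3d_fw_impl(const NumericVector& x, const IntegerVector& xd,
                                    const NumericVector& w, const IntegerVector& wd,
                                    const NumericVector& b, const IntegerVector& st,
                                    const IntegerVector& pd) {
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3], N = xd[4];
  const int K1 = wd[0], K2 = wd[1], K3 = wd[2], Cout = wd[4];
  const int s1 = st[0], s2 = st[1], s3 = st[2];
  const int p1 = pd[0], p2 = pd[1], p3 = pd[2];
  const int O1 = out_dim(D1, K1, s1, p1), O2 = out_dim(D2, K2, s2, p2),
            O3 = out_dim(D3, K3, s3, p3);
  if (O1 < 1 || O2 < 1 || O3 < 1)
    stop("conv3d: input too small for kernel/stride (output dims %d x %d x %d)", O1, O2, O3);
  const arma::uword L = static_cast<arma::uword>(O1) * O2 * O3;
  const arma::uword R = static_cast<arma::uword>(K1) * K2 * K3 * C;
  const int P1 = D1 + 2 * p1, P2 = D2 + 2 * p2, P3 = D3 + 2 * p3;

  arma::Mat<T> W2(R, Cout);
  for (arma::uword i = 0; i < R * (arma::uword)Cout; ++i)
    W2.memptr()[i] = static_cast<T>(w[i]);
  arma::Col<T> bv(Cout);
  for (int c = 0; c < Cout; ++c) bv[c] = static_cast<T>(b[c]);

  NumericVector out(L * Cout * (arma::uword)N);
  arma::Col<T> xp;
  arma::Mat<T> Pt;
  const size_t svol = (size_t)D1 * D2 * D3 * C;
  for (int n = 0; n < N; ++n) {
    pad_volume<T>(REAL(x) + (size_t)n * svol, D1, D2, D3, C, p1, p2, p3, xp);
    im2col<T>(xp, P1, P2, P3, C, K1, K2, K3, s1, s2, s3, O1, O2, O3, Pt);
    arma::Mat<T> O = Pt * W2;
    O.each_row() += bv.t();
    double* od = REAL(out) + (size_t)n * L * Cout;
    const T* om = O.memptr();
    for (arma::uword i = 0; i < L * (arma::uword)Cout; ++i) od[i] = om[i];
  }
  out.attr("dim") = IntegerVector::create(O1, O2, O3, Cout, N);
  return out;
}

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, IntegerVector xdim,
                        NumericVector w, IntegerVector wdim,
                        NumericVector b, IntegerVector stride,
                        IntegerVector pad, bool single) {
  return single ? conv3d_fw_impl<float>(x, xdim, w, wdim, b, stride, pad)
                : conv3d_fw_impl<double>(x, xdim, w, wdim, b, stride, pad);
}

template <typename T>
static NumericVector conv3d_bwx_impl(const NumericVector& go, const IntegerVector& od,
                                     const NumericVector& w, const IntegerVector& wd,
                                     const IntegerVector& xd, const IntegerVector& st,
                                     const IntegerVector& pd) {
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3], N = xd[4];
  const int K1 = wd[0], K2 = wd[1], K3 = wd[2], Cout = wd[4];
  const int O1 = od[0], O2 = od[1], O3 = od[2];
  const int s1 = st[0], s2 = st[1], s3 = st[2];
  const int p1 = pd[0], p2 = pd[1], p3 = pd[2];
  const int P1 = D1 + 2 * p1, P2 = D2 + 2 * p2, P3 = D3 + 2 * p3;
  const arma::uword L = static_cast<arma::uword>(O1) * O2 * O3;
  const arma::uword R = static_cast<arma::uword>(K1) * K2 * K3 * C;

  arma::Mat<T> W2(R, Cout);
  for (arma::uword i = 0; i < R * (arma::uword)Cout; ++i)
    W2.memptr()[i] = static_cast<T>(w[i]);

  NumericVector gx((size_t)D1 * D2 * D3 * C * N);
  arma::Col<T> gxp(static_cast<arma::uword>(P1) * P2 * P3 * C);
  for (int n = 0; n < N; ++n) {
    arma::Mat<T> gO(L, Cout);
    const double* god = REAL(go) + (size_t)n * L * Cout;
    for (arma::uword i = 0; i < L * (arma::uword)Cout; ++i)
      gO.memptr()[i] = static_cast<T>(god[i]);
    arma::Mat<T> gP = gO * W2.t();  // L x R
    gxp.zeros();
    T* gxpd = gxp.memptr();
    arma::uword r = 0;
    for (int c = 0; c < C; ++c)
      for (int k3 = 0; k3 < K3; ++k3)
        for (int k2 = 0; k2 < K2; ++k2)
          for (int k1 = 0; k1 < K1; ++k1, ++r) {
            const T* col = gP.colptr(r);
            arma::uword l = 0;
            for (int o3 = 0; o3 < O3; ++o3)
              for (int o2 = 0; o2 < O2; ++o2) {
                T* dst = gxpd + (size_t)k1 +
                         (size_t)(o2 * s2 + k2) * P1 +
                         (size_t)(o3 * s3 + k3) * P1 * P2 +
                         (size_t)c * P1 * P2 * P3;
                for (int o1 = 0; o1 < O1; ++o1) dst[o1 * s1] += col[l++];
              }
          }
    // crop padding away
    double* gxd = REAL(gx) + (size_t)n * D1 * D2 * D3 * C;
    for (int c = 0; c < C; ++c)
      for (int d3 = 0; d3 < D3; ++d3)
        for (int d2 = 0; d2 < D2; ++d2) {
          const T* src = gxpd + (size_t)p1 + (size_t)(d2 + p2) * P1 +
                         (size_t)(d3 + p3) * P1 * P2 + (size_t)c * P1 * P2 * P3;
          double* dst = gxd + (size_t)d2 * D1 + (size_t)d3 * D1 * D2 +
                        (size_t)c * D1 * D2 * D3;
          for (int d1 = 0; d1 < D1; ++d1) dst[d1] = static_cast<double>(src[d1]);
        }
  }
  gx.attr("dim") = IntegerVector::create(D1, D2, D3, C, N);
  return gx;
}

// [[Rcpp::export(name = ".conv3d_bw_input")]]
NumericVector conv3d_bw_input(NumericVector gout, IntegerVector odim,
                              NumericVector w, IntegerVector wdim,
                              IntegerVector xdim, IntegerVector stride,
                              IntegerVector pad, bool single) {
  return single ? conv3d_bwx_impl<float>(gout, odim, w, wdim, xdim, stride, pad)
                : conv3d_bwx_impl<double>(gout, odim, w, wdim, xdim, stride, pad);
}

template <typename T>
static List conv3d_bww_impl(const NumericVector& x, const IntegerVector& xd,
                            const NumericVector& go, const IntegerVector& od,
                            const IntegerVector& wd, const IntegerVector& st,
                            const IntegerVector& pd) {
  const int D1 = xd[0], D2 = xd[1], D3 = xd[2], C = xd[3], N = xd[4];
  const int K1 = wd[0], K2 = wd[1], K3 = wd[2], Cout = wd[4];
  const int O1 = od[0], O2 = od[1], O3 = od[2];
  const int s1 = st[0], s2 = st[1], s3 = st[2];
  const int p1 = pd[0], p2 = pd[1], p3 = pd[2];
  const int P1 = D1 + 2 * p1, P2 = D2 + 2 * p2, P3 = D3 + 2 * p3;
  const arma::uword L = static_cast<arma::uword>(O1) * O2 * O3;
  const arma::uword R = static_cast<arma::uword>(K1) * K2 * K3 * C;

  arma::Mat<T> gW(R, Cout, arma::fill::zeros);
  arma::Col<T> gB(Cout, arma::fill::zeros);
  arma::Col<T> xp;
  arma::Mat<T> Pt;
  const size_t svol = (size_t)D1 * D2 * D3 * C;
  for (int n = 0; n < N; ++n) {
    pad_volume<T>(REAL(x) + (size_t)n * svol, D1, D2, D3, C, p1, p2, p3, xp);
    im2col<T>(xp, P1, P2, P3, C, K1, K2, K3, s1, s2, s3, O1, O2, O3, Pt);
    arma::Mat<T> gO(L, Cout);
    const double* god = REAL(go) + (size_t)n * L * Cout;
    for (arma::uword i = 0; i < L * (arma::uword)Cout; ++i)
      gO.memptr()[i] = static_cast<T>(god[i]);
    gW += Pt.t() * gO;
    gB += arma::sum(gO, 0).t();
  }
  NumericVector gw(R * (arma::uword)Cout), gb(Cout);
  for (arma::uword i = 0; i < R * (arma::uword)Cout; ++i) gw[i] = gW.memptr()[i];
  for (int c = 0; c < Cout; ++c) gb[c] = gB[c];
  gw.attr("dim") = IntegerVector::create(K1, K2, K3, C, Cout);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".conv3d_bw_weight")]]
List conv3d_bw_weight(NumericVector x, IntegerVector xdim,
                      NumericVector gout, IntegerVector odim,
                      IntegerVector wdim, IntegerVector stride,
                      IntegerVector pad, bool single) {
  return single ? conv3d_bww_impl<float>(x, xdim, gout, odim, wdim, stride, pad)
                : conv3d_bww_impl<double>(x, xdim, gout, odim, wdim, stride, pad);
}

// Max pooling with floor semantics: trailing voxels that do not fill a full
// window are dropped. Returns pooled values and 1-based linear argmax indices
// into the input array (used for the backward scatter).
// [[Rcpp::export(name = ".maxpool3d_fw")]]
List maxpool3d_fw(NumericVector x, IntegerVector xdim,
                  IntegerVector window, IntegerVector stride) {
  const int D1 = xdim[0], D2 = xdim[1], D3 = xdim[2], C = xdim[3], N = xdim[4];
  const int w1 = window[0], w2 = window[1], w3 = window[2];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int O1 = (D1 - w1) / s1 + 1, O2 = (D2 - w2) / s2 + 1, O3 = (D3 - w3) / s3 + 1;
  if (O1 < 1 || O2 < 1 || O3 < 1)
    stop("maxpool3d: input smaller than pooling window");
  const size_t L = (size_t)O1 * O2 * O3;
  NumericVector out(L * C * N);
  IntegerVector arg(L * C * N);
  const double* xd = REAL(x);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)c + (size_t)n * C) * D1 * D2 * D3;
      for (int o3 = 0; o3 < O3; ++o3)
        for (int o2 = 0; o2 < O2; ++o2)
          for (int o1 = 0; o1 < O1; ++o1, ++o) {
            double best = -1e308;
            size_t besti = 0;
            for (int k3 = 0; k3 < w3; ++k3)
              for (int k2 = 0; k2 < w2; ++k2)
                for (int k1 = 0; k1 < w1; ++k1) {
                  const size_t idx = base + (size_t)(o1 * s1 + k1) +
                                     (size_t)(o2 * s2 + k2) * D1 +
                                     (size_t)(o3 * s3 + k3) * D1 * D2;
                  if (xd[idx] > best) { best = xd[idx]; besti = idx; }
                }
            out[o] = best;
            arg[o] = (int)(besti + 1);
          }
    }
  out.attr("dim") = IntegerVector::create(O1, O2, O3, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bw")]]
NumericVector maxpool3d_bw(NumericVector gout, IntegerVector argmax, int xlen) {
  NumericVector gx(xlen);
  const int n = gout.size();
  for (int i = 0; i < n; ++i) gx[argmax[i] - 1] += gout[i];
  return gx;
}
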