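// Depthwise 3-D convolution and fused activation/normalization kernels.
//
// Feature arrays are channel-first, column-major: element (c, d, h, w) of a
// (C, D, H, W) array sits at c + C*(d + D*(h + H*w)), all indices 0-based.
// Depthwise kernels are (C, KD, KH, KW).  Loops are ordered so the inner
// runs are contiguous in memory (channel + depth fastest).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector dwconv3d_fwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                               const NumericVector& w, const IntegerVector& wdim) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int KD = wdim[1], KH = wdim[2], KW = wdim[3];
  const int pd = (KD - 1) / 2, ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  NumericVector y(x.size());
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  const size_t strideH = (size_t)C * D, strideW = strideH * H;
  for (int kw = 0; kw < KW; ++kw) {
    for (int kh = 0; kh < KH; ++kh) {
      for (int kd = 0; kd < KD; ++kd) {
        const double* wk = wp + (size_t)C * (kd + (size_t)KD * (kh + (size_t)KH * kw));
        const int dsh = kd - pd, hsh = kh - ph, wsh = kw - pw;
        const int d0 = std::max(0, -dsh), d1 = std::min(D, D - dsh);
        if (d1 <= d0) continue;
        for (int w2 = std::max(0, -wsh); w2 < std::min(W, W - wsh); ++w2) {
          for (int h2 = std::max(0, -hsh); h2 < std::min(H, H - hsh); ++h2) {
            double* dst = yp + strideW * w2 + strideH * h2 + (size_t)C * d0;
            const double* src = xp + strideW * (w2 + wsh) + strideH * (h2 + hsh) + (size_t)C * (d0 + dsh);
            const int n = d1 - d0;
            for (int dd = 0; dd < n; ++dd) {
              const size_t o = (size_t)C * dd;
              for (int c = 0; c < C; ++c) dst[o + c] += wk[c] * src[o + c];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = xdim;
  return y;
}

// [[Rcpp::export]]
List dwconv3d_bwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                      const NumericVector& w, const IntegerVector& wdim,
                      const NumericVector& dy) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int KD = wdim[1], KH = wdim[2], KW = wdim[3];
  const int pd = (KD - 1) / 2, ph = (KH - 1) / 2, pw = (KW - 1) / 2;
  NumericVector dx(x.size());
  NumericVector dw(w.size());
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  const size_t strideH = (size_t)C * D, strideW = strideH * H;
  std::vector<double> wacc(C);
  for (int kw = 0; kw < KW; ++kw) {
    for (int kh = 0; kh < KH; ++kh) {
      for (int kd = 0; kd < KD; ++kd) {
        const size_t wo = (size_t)C * (kd + (size_t)KD * (kh + (size_t)KH * kw));
        const double* wk = wp + wo;
        double* dwk = dwp + wo;
        std::fill(wacc.begin(), wacc.end(), 0.0);
        const int dsh = kd - pd, hsh = kh - ph, wsh = kw - pw;
        const int d0 = std::max(0, -dsh), d1 = std::min(D, D - dsh);
        if (d1 <= d0) continue;
        for (int w2 = std::max(0, -wsh); w2 < std::min(W, W - wsh); ++w2) {
          for (int h2 = std::max(0, -hsh); h2 < std::min(H, H - hsh); ++h2) {
            const double* g = gp + strideW * w2 + strideH * h2 + (size_t)C * d0;
            const size_t so = strideW * (w2 + wsh) + strideH * (h2 + hsh) + (size_t)C * (d0 + dsh);
            const double* src = xp + so;
            double* dsrc = dxp + so;
            const int n = d1 - d0;
            for (int dd = 0; dd < n; ++dd) {
              const size_t o = (size_t)C * dd;
              for (int c = 0; c < C; ++c) {
                dsrc[o + c] += wk[c] * g[o + c];
                wacc[c] += src[o + c] * g[o + c];
              }
            }
          }
        }
        for (int c = 0; c < C; ++c) dwk[c] += wacc[c];
      }
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Fused leaky ReLU + per-channel instance normalization.
// Input x (C x V view); returns y = gamma * xhat + beta where
// xhat = (a - mean(a)) / sqrt(var(a) + eps), a = leaky_relu(x).
// The backward pass recovers the activation's negativity mask from
// xhat < -mu * inv (a < 0 iff x < 0), so no mask is stored.
// [[Rcpp::export]]
List act_norm_fwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                      const NumericVector& gamma, const NumericVector& beta,
                      const double slope, const double eps) {
  const int C = xdim[0];
  const R_xlen_t N = x.size();
  const R_xlen_t V = N / C;
  NumericVector y(N), xhat(N);
  NumericVector inv(C), mu(C);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (R_xlen_t v = 0; v < V; ++v) {
    const R_xlen_t o = (R_xlen_t)C * v;
    for (int c = 0; c < C; ++c) {
      double a = xp[o + c];
      if (a < 0) a *= slope;
      hp[o + c] = a;           // activation stored, normalized in place below
      s1[c] += a;
      s2[c] += a * a;
    }
  }
  for (int c = 0; c < C; ++c) {
    const double m = s1[c] / V;
    const double var = s2[c] / V - m * m;
    inv[c] = 1.0 / std::sqrt(var > 0 ? var + eps : eps);
    mu[c] = m;
  }
  for (R_xlen_t v = 0; v < V; ++v) {
    const R_xlen_t o = (R_xlen_t)C * v;
    for (int c = 0; c < C; ++c) {
      const double xh = (hp[o + c] - mu[c]) * inv[c];
      hp[o + c] = xh;
      yp[o + c] = gamma[c] * xh + beta[c];
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv, _["mu"] = mu);
}

// Backward of the fused leaky ReLU + instance norm.
// [[Rcpp::export]]
List act_norm_bwd_cpp(const NumericVector& dy, const IntegerVector& xdim,
                      const NumericVector& gamma, const NumericVector& xhat,
                      const NumericVector& inv, const NumericVector& mu,
                      const double slope) {
  const int C = xdim[0];
  const R_xlen_t N = dy.size();
  const R_xlen_t V = N / C;
  NumericVector dx(N);
  NumericVector dgamma(C), dbeta(C);
  const double* gp = dy.begin();
  const double* hp = xhat.begin();
  double* dp = dx.begin();
  std::vector<double> m1(C, 0.0), m2(C, 0.0), thr(C);
  for (int c = 0; c < C; ++c) thr[c] = -mu[c] * inv[c];
  for (R_xlen_t v = 0; v < V; ++v) {
    const R_xlen_t o = (R_xlen_t)C * v;
    for (int c = 0; c < C; ++c) {
      const double g = gp[o + c];
      const double xh = hp[o + c];
      dgamma[c] += g * xh;
      dbeta[c] += g;
      const double dxh = gamma[c] * g;
      m1[c] += dxh;
      m2[c] += dxh * xh;
    }
  }
  for (int c = 0; c < C; ++c) { m1[c] /= V; m2[c] /= V; }
  for (R_xlen_t v = 0; v < V; ++v) {
    const R_xlen_t o = (R_xlen_t)C * v;
    for (int c = 0; c < C; ++c) {
      double d = inv[c] * (gamma[c] * gp[o + c] - m1[c] - hp[o + c] * m2[c]);
      if (hp[o + c] < thr[c]) d *= slope;
      dp[o + c] = d;
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
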