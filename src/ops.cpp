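// Hot elementwise kernels for the network layers. Everything here is a
// straight loop over a numeric matrix; the surrounding R code owns all
// shape logic.
#include <Rcpp.h>
using namespace Rcpp;

// y[i,j] = m[i,j] * s[j]
// [[Rcpp::export]]
NumericMatrix cpp_scale_cols(const NumericMatrix& m, const NumericVector& s) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double sj = s[j];
    const double* src = &m(0, j);
    double* dst = &out(0, j);
    for (int i = 0; i < nr; ++i) dst[i] = src[i] * sj;
  }
  return out;
}

// y[i,j] = m[i,j] + s[j]
// [[Rcpp::export]]
NumericMatrix cpp_add_cols(const NumericMatrix& m, const NumericVector& s) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double sj = s[j];
    const double* src = &m(0, j);
    double* dst = &out(0, j);
    for (int i = 0; i < nr; ++i) dst[i] = src[i] + sj;
  }
  return out;
}

// y[i,j] = (m[i,j] - mu[j]) * a[j] * g[j] + b[j]  (fused batch-norm affine)
// [[Rcpp::export]]
NumericMatrix cpp_bn_affine(const NumericMatrix& m, const NumericVector& mu,
                            const NumericVector& a, const NumericVector& g,
                            const NumericVector& b) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double sj = a[j] * g[j], cj = b[j], mj = mu[j];
    const double* src = &m(0, j);
    double* dst = &out(0, j);
    for (int i = 0; i < nr; ++i) dst[i] = (src[i] - mj) * sj + cj;
  }
  return out;
}

// ELU, elementwise
// [[Rcpp::export]]
NumericVector cpp_elu(const NumericVector& x) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  out.attr("dim") = x.attr("dim");
  return out;
}

// dL/dx from dL/dy and y = elu(x): dx = dy * (y > 0 ? 1 : y + 1)
// [[Rcpp::export]]
NumericVector cpp_elu_grad(const NumericVector& y, const NumericVector& dy) {
  const R_xlen_t n = y.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = dy[i] * (y[i] > 0 ? 1.0 : y[i] + 1.0);
  out.attr("dim") = dy.attr("dim");
  return out;
}

// Depthwise 'same' temporal convolution over a (T, N, dep) tensor given as
// a (T, N*dep) matrix; one k-tap filter per depth channel.
// [[Rcpp::export]]
NumericMatrix cpp_dwconv_fwd(const NumericMatrix& x, const NumericMatrix& w,
                             const int n_trials) {
  const int T = x.nrow(), S = x.ncol(), k = w.nrow();
  const int pl = (k - 1) / 2;
  NumericMatrix out(T, S);
  for (int s = 0; s < S; ++s) {
    const int depth = s / n_trials;
    const double* col = &x(0, s);
    double* dst = &out(0, s);
    for (int t = 0; t < T; ++t) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) {
        const int src = t - pl + j;
        if (src >= 0 && src < T) acc += col[src] * w(j, depth);
      }
      dst[t] = acc;
    }
  }
  return out;
}

// Backward of cpp_dwconv_fwd: returns dx (T, N*dep) and accumulates dw.
// [[Rcpp::export]]
List cpp_dwconv_bwd(const NumericMatrix& x, const NumericMatrix& w,
                    const NumericMatrix& dy, const int n_trials) {
  const int T = x.nrow(), S = x.ncol(), k = w.nrow();
  const int pl = (k - 1) / 2;
  const int dep = w.ncol();
  NumericMatrix dx(T, S);
  NumericMatrix dw(k, dep);
  for (int s = 0; s < S; ++s) {
    const int depth = s / n_trials;
    const double* colx = &x(0, s);
    const double* coldy = &dy(0, s);
    double* coldx = &dx(0, s);
    double* dwcol = &dw(0, depth);
    const double* wcol = &w(0, depth);
    for (int t = 0; t < T; ++t) {
      const double g = coldy[t];
      if (g == 0.0) continue;
      const int j0 = std::max(0, pl - t);
      const int j1 = std::min(k, T - t + pl);
      const double* xb = colx + t - pl;
      double* db = coldx + t - pl;
      for (int j = j0; j < j1; ++j) {
        dwcol[j] += xb[j] * g;
        db[j] += wcol[j] * g;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Row-wise softmax with max-shift.
// [[Rcpp::export]]
NumericMatrix cpp_softmax_rows(const NumericMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    double mx = m(i, 0);
    for (int j = 1; j < nc; ++j) if (m(i, j) > mx) mx = m(i, j);
    double s = 0.0;
    for (int j = 0; j < nc; ++j) { const double e = std::exp(m(i, j) - mx); out(i, j) = e; s += e; }
    const double inv = 1.0 / s;
    for (int j = 0; j < nc; ++j) out(i, j) *= inv;
  }
  return out;
}

// Fused batch/layer-norm forward over columns: returns xhat and
// out = xhat * gamma + beta in one pass.
// [[Rcpp::export]]
List cpp_bn_apply(const NumericMatrix& m, const NumericVector& mu,
                  const NumericVector& inv_sd, const NumericVector& g,
                  const NumericVector& b) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix xhat(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double mj = mu[j], aj = inv_sd[j], gj = g[j], bj = b[j];
    const double* src = &m(0, j);
    double* xh = &xhat(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < nr; ++i) {
      const double v = (src[i] - mj) * aj;
      xh[i] = v;
      o[i] = v * gj + bj;
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// Fused batch-norm backward (training mode): given xhat, dout, gamma,
// inv_sd, computes dgamma, dbeta and dx in two passes.
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& xhat, const NumericMatrix& dout,
                const NumericVector& g, const NumericVector& inv_sd,
                const bool batch_stats) {
  const int nr = xhat.nrow(), nc = xhat.ncol();
  NumericVector dgamma(nc), dbeta(nc);
  NumericMatrix dx(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* xh = &xhat(0, j);
    const double* dy = &dout(0, j);
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < nr; ++i) {
      s1 += dy[i];
      s2 += dy[i] * xh[i];
    }
    dgamma[j] = s2;
    dbeta[j] = s1;
    const double gj = g[j], aj = inv_sd[j];
    double* o = &dx(0, j);
    if (batch_stats) {
      const double m1 = gj * s1 / nr, m2 = gj * s2 / nr;
      for (int i = 0; i < nr; ++i)
        o[i] = (gj * dy[i] - m1 - xh[i] * m2) * aj;
    } else {
      for (int i = 0; i < nr; ++i) o[i] = gj * dy[i] * aj;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
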