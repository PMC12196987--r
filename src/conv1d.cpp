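// 1-D convolution and instance-normalization kernels. Signals are
// (N, L, C) arrays: batch x length x channels, column-major, so each
// (t, c) column holds N contiguous samples. The conv weight matrix W is
// (k*Cin, Cout) with row order (j-1)*Cin + c for kernel offset j and input
// channel c, matching the column order of the im2col matrix built here.
// R-side wrappers pass plain numeric arrays; views are taken without
// copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static ivec3 dims3(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected a 3-d array");
  return {d[0], d[1], d[2]};
}

static mat im2col(const double* x, int N, int L, int Cin,
                  int k, int stride, int pad, int Lout) {
  mat Xcol((size_t)N * Lout, (size_t)k * Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * N * L;
    for (int j = 0; j < k; ++j) {
      double* col = Xcol.colptr((size_t)j * Cin + c);
      for (int t = 0; t < Lout; ++t) {
        int src = t * stride + j - pad;
        if (src < 0 || src >= L) continue;
        std::copy(xc + (size_t)src * N, xc + (size_t)(src + 1) * N,
                  col + (size_t)t * N);
      }
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
Rcpp::NumericVector conv1d_fwd_cpp(const Rcpp::NumericVector& X,
                                   const arma::mat& W, const arma::vec& b,
                                   int stride, int pad, int k) {
  ivec3 d = dims3(X);
  const int N = d[0], L = d[1], Cin = d[2];
  const int Cout = W.n_cols;
  const int Lout = (L + 2 * pad - k) / stride + 1;
  mat Xcol = im2col(X.begin(), N, L, Cin, k, stride, pad, Lout);
  Rcpp::NumericVector out(Rcpp::Dimension(N, Lout, Cout));
  mat Y(out.begin(), (size_t)N * Lout, Cout, false, true);
  Y = Xcol * W;
  Y.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const Rcpp::NumericVector& X, const arma::mat& W,
                          const Rcpp::NumericVector& dY,
                          int stride, int pad, int k) {
  ivec3 d = dims3(X);
  const int N = d[0], L = d[1], Cin = d[2];
  ivec3 dd = dims3(dY);
  const int Lout = dd[1], Cout = dd[2];
  const mat dYm(const_cast<double*>(dY.begin()), (size_t)N * Lout, Cout,
                false, true);
  mat Xcol = im2col(X.begin(), N, L, Cin, k, stride, pad, Lout);
  mat dW = Xcol.t() * dYm;
  vec db = sum(dYm, 0).t();
  mat dXcol = dYm * W.t();
  Rcpp::NumericVector dXout(Rcpp::Dimension(N, L, Cin));
  double* dx = dXout.begin();
  for (int c = 0; c < Cin; ++c) {
    double* dxc = dx + (size_t)c * N * L;
    for (int j = 0; j < k; ++j) {
      const double* col = dXcol.colptr((size_t)j * Cin + c);
      for (int t = 0; t < Lout; ++t) {
        int src = t * stride + j - pad;
        if (src < 0 || src >= L) continue;
        double* xp = dxc + (size_t)src * N;
        const double* dp = col + (size_t)t * N;
        for (int i = 0; i < N; ++i) xp[i] += dp[i];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dXout,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List inorm_fwd_cpp(const Rcpp::NumericVector& X, double eps) {
  ivec3 d = dims3(X);
  const int N = d[0], L = d[1], C = d[2];
  Rcpp::NumericVector xhat(Rcpp::Dimension(N, L, C));
  Rcpp::NumericMatrix istd(N, C);
  const double* x = X.begin();
  double* xh = xhat.begin();
  std::vector<double> mu(N), is(N);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * N * L;
    double* hc = xh + (size_t)c * N * L;
    std::fill(mu.begin(), mu.end(), 0.0);
    std::fill(is.begin(), is.end(), 0.0);
    for (int t = 0; t < L; ++t) {
      const double* p = xc + (size_t)t * N;
      for (int i = 0; i < N; ++i) mu[i] += p[i];
    }
    for (int i = 0; i < N; ++i) mu[i] /= L;
    for (int t = 0; t < L; ++t) {
      const double* p = xc + (size_t)t * N;
      for (int i = 0; i < N; ++i) {
        double dv = p[i] - mu[i];
        is[i] += dv * dv;
      }
    }
    for (int i = 0; i < N; ++i)
      is[i] = 1.0 / std::sqrt(is[i] / L + eps);
    for (int t = 0; t < L; ++t) {
      const double* p = xc + (size_t)t * N;
      double* h = hc + (size_t)t * N;
      for (int i = 0; i < N; ++i) h[i] = (p[i] - mu[i]) * is[i];
    }
    for (int i = 0; i < N; ++i) istd(i, c) = is[i];
  }
  return Rcpp::List::create(Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::NumericVector inorm_bwd_cpp(const Rcpp::NumericVector& dY,
                                  const Rcpp::NumericVector& xhat,
                                  const Rcpp::NumericMatrix& istd) {
  ivec3 d = dims3(dY);
  const int N = d[0], L = d[1], C = d[2];
  Rcpp::NumericVector dXout(Rcpp::Dimension(N, L, C));
  const double* dy = dY.begin();
  const double* xh = xhat.begin();
  double* dx = dXout.begin();
  std::vector<double> m1(N), m2(N);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy + (size_t)c * N * L;
    const double* xhc = xh + (size_t)c * N * L;
    double* dxc = dx + (size_t)c * N * L;
    std::fill(m1.begin(), m1.end(), 0.0);
    std::fill(m2.begin(), m2.end(), 0.0);
    for (int t = 0; t < L; ++t) {
      const double* p = dyc + (size_t)t * N;
      const double* h = xhc + (size_t)t * N;
      for (int i = 0; i < N; ++i) {
        m1[i] += p[i];
        m2[i] += p[i] * h[i];
      }
    }
    for (int i = 0; i < N; ++i) { m1[i] /= L; m2[i] /= L; }
    for (int t = 0; t < L; ++t) {
      const double* p = dyc + (size_t)t * N;
      const double* h = xhc + (size_t)t * N;
      double* o = dxc + (size_t)t * N;
      for (int i = 0; i < N; ++i)
        o[i] = istd(i, c) * (p[i] - m1[i] - h[i] * m2[i]);
    }
  }
  return dXout;
}
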