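// Elementwise / per-channel layer kernels. Channel is the fastest
// dimension of every tensor, so a per-channel parameter indexes as i % C.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::cube cpp_prelu_forward(const arma::cube& x, const arma::vec& a) {
  cube y = x;
  const int C = x.n_rows;
  double* p = y.memptr();
  const size_t n = y.n_elem;
  for (size_t i = 0; i < n; ++i) {
    if (p[i] < 0) p[i] *= a[i % C];
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_prelu_backward(const arma::cube& x, const arma::vec& a,
                              const arma::cube& dy) {
  cube dx = dy;
  vec da(a.n_elem, fill::zeros);
  const int C = x.n_rows;
  const double* px = x.memptr();
  const double* pd = dy.memptr();
  double* pdx = dx.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) {
    if (px[i] < 0) {
      const int c = i % C;
      pdx[i] = pd[i] * a[c];
      da[c] += pd[i] * px[i];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("da") = da);
}

// [[Rcpp::export]]
arma::cube cpp_lrelu_forward(const arma::cube& x, double slope) {
  cube y = x;
  double* p = y.memptr();
  const size_t n = y.n_elem;
  for (size_t i = 0; i < n; ++i) {
    if (p[i] < 0) p[i] *= slope;
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_lrelu_backward(const arma::cube& x, double slope,
                              const arma::cube& dy) {
  cube dx = dy;
  const double* px = x.memptr();
  double* p = dx.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) {
    if (px[i] < 0) p[i] *= slope;
  }
  return dx;
}

// batch-norm forward given per-channel mean and 1/sd; returns y and xhat
// [[Rcpp::export]]
Rcpp::List cpp_bn_apply(const arma::cube& x, const arma::vec& mu,
                        const arma::vec& inv, const arma::vec& gamma,
                        const arma::vec& beta) {
  const int C = x.n_rows;
  cube xhat = x, y(x.n_rows, x.n_cols, x.n_slices);
  double* ph = xhat.memptr();
  double* py = y.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) {
    const int c = i % C;
    ph[i] = (ph[i] - mu[c]) * inv[c];
    py[i] = ph[i] * gamma[c] + beta[c];
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat);
}

// batch-norm backward (training form): needs xhat, inv, gamma
// [[Rcpp::export]]
Rcpp::List cpp_bn_backward(const arma::cube& xhat, const arma::vec& inv,
                           const arma::vec& gamma, const arma::cube& dy,
                           bool train) {
  const int C = xhat.n_rows;
  const size_t n = xhat.n_elem;
  const double m = (double)n / C;
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  const double* ph = xhat.memptr();
  const double* pd = dy.memptr();
  for (size_t i = 0; i < n; ++i) {
    const int c = i % C;
    dgamma[c] += pd[i] * ph[i];
    dbeta[c] += pd[i];
  }
  cube dx(xhat.n_rows, xhat.n_cols, xhat.n_slices);
  double* px = dx.memptr();
  if (train) {
    // s1 = sum(dxhat), s2 = sum(dxhat * xhat) per channel; dxhat = dy*gamma
    vec s1 = dbeta % gamma, s2 = dgamma % gamma;
    for (size_t i = 0; i < n; ++i) {
      const int c = i % C;
      px[i] = (pd[i] * gamma[c] - s1[c] / m - ph[i] * (s2[c] / m)) * inv[c];
    }
  } else {
    for (size_t i = 0; i < n; ++i) {
      const int c = i % C;
      px[i] = pd[i] * gamma[c] * inv[c];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// per-channel sums of x and x^2 (for batch statistics)
// [[Rcpp::export]]
Rcpp::List cpp_ch_moments(const arma::cube& x) {
  const int C = x.n_rows;
  vec s(C, fill::zeros), s2(C, fill::zeros);
  const double* p = x.memptr();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) {
    const int c = i % C;
    s[c] += p[i];
    s2[c] += p[i] * p[i];
  }
  return Rcpp::List::create(Rcpp::Named("sum") = s, Rcpp::Named("sumsq") = s2);
}
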