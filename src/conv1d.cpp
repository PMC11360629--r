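// 1D convolution kernels (im2col + GEMM).
//
// Tensors arrive as (channels, length, batch) cubes, matching the R-side
// layout. Padding is implicit: taps that fall outside [0, len) read zeros
// on the forward pass and are skipped on the backward scatter.
//
// Everything runs in double precision; the test suite checks these kernels
// against an independent scalar reference implementation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col_d(const cube& x, int k, int stride, int pad_l,
                     int out_len) {
  const int inc = x.n_rows, len = x.n_cols, B = x.n_slices;
  mat P(k * inc, (size_t)out_len * B, fill::zeros);
  for (int bi = 0; bi < B; ++bi) {
    const mat& xs = x.slice(bi);
    for (int t = 0; t < out_len; ++t) {
      const int base = t * stride - pad_l;
      double* col = P.colptr((size_t)bi * out_len + t);
      const int j0 = std::max(0, -base);
      const int j1 = std::min(k, len - base);
      for (int j = j0; j < j1; ++j) {
        std::memcpy(col + (size_t)j * inc, xs.colptr(base + j),
                    inc * sizeof(double));
      }
    }
  }
  return P;
}

// Forward pass; the im2col matrix is returned alongside the output so the
// backward pass can reuse it without a rebuild. It travels as an ordinary
// R matrix, so the garbage collector sees its true size.
// [[Rcpp::export]]
Rcpp::List cpp_conv1d_forward(const arma::cube& x, const arma::mat& W,
                              const arma::vec& b, int k, int stride,
                              int pad_l, int out_len) {
  const int B = x.n_slices;
  mat P = im2col_d(x, k, stride, pad_l, out_len);
  mat Y = W * P;
  Y.each_col() += b;
  cube y(W.n_rows, out_len, B);
  std::copy(Y.begin(), Y.end(), y.begin());
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_backward(const arma::mat& P, const arma::mat& W,
                               const arma::cube& dy, int k, int stride,
                               int pad_l, int inc, int len) {
  const int out_ch = dy.n_rows, out_len = dy.n_cols;
  const int B = dy.n_slices;
  const mat Dm(const_cast<double*>(dy.memptr()), out_ch,
                (size_t)out_len * B, false, true);
  mat dW = Dm * P.t();
  vec db = sum(Dm, 1);
  mat dP = W.t() * Dm;
  cube dx(inc, len, B, fill::zeros);
  for (int bi = 0; bi < B; ++bi) {
    mat& dxs = dx.slice(bi);
    for (int t = 0; t < out_len; ++t) {
      const int base = t * stride - pad_l;
      const double* col = dP.colptr((size_t)bi * out_len + t);
      const int j0 = std::max(0, -base);
      const int j1 = std::min(k, len - base);
      for (int j = j0; j < j1; ++j) {
        double* dst = dxs.colptr(base + j);
        const double* src = col + (size_t)j * inc;
        for (int c = 0; c < inc; ++c) dst[c] += src[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
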