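// 3x3 convolution kernels for the residual learning unit.
//
// Activations are channels x pixels matrices over a batch of vectorized
// n x n images (sample-major, column-major pixel order). A 3x3 convolution
// is expressed as an im2col gather (9 stacked shifted copies with zero
// fill at image borders) followed by a single BLAS product, in both the
// forward and the backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int DI[9] = {-1, 0, 1, -1, 0, 1, -1, 0, 1};
static const int DJ[9] = {-1, -1, -1, 0, 0, 0, 1, 1, 1};

// Stack the 9 shifted copies of A: block k holds A shifted by offset
// (DI[k], DJ[k]) with zeros where the source pixel falls outside its image.
static mat im2col9(const mat& A, const int n, const int batch) {
  const uword cin = A.n_rows;
  const uword N = A.n_cols;
  mat out(9 * cin, N, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int di = DI[k], dj = DJ[k];
    const int c_lo = std::max(0, -dj), c_hi = std::min(n, n - dj);
    const int r_lo = std::max(0, -di), r_hi = std::min(n, n - di);
    if (c_lo >= c_hi || r_lo >= r_hi) continue;
    const int run = r_hi - r_lo;
    for (int s = 0; s < batch; ++s) {
      const uword base = (uword)s * n * n;
      for (int c = c_lo; c < c_hi; ++c) {
        const uword dst = base + (uword)c * n + r_lo;
        const uword src = dst + di + (uword)dj * n;
        out.submat(k * cin, dst, (k + 1) * cin - 1, dst + run - 1) =
          A.cols(src, src + run - 1);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
arma::mat conv_fwd_cpp(const arma::mat& A, const arma::mat& Wcat,
                       const arma::vec& b, const int n, const int batch) {
  mat Acat = im2col9(A, n, batch);
  mat Y = Wcat.t() * Acat;
  Y.each_col() += b;
  return Y;
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
Rcpp::List conv_bwd_cpp(const arma::mat& dY, const arma::mat& A,
                        const arma::mat& Wcat, const int n, const int batch) {
  const uword cin = A.n_rows;
  mat Acat = im2col9(A, n, batch);
  mat dWcat = Acat * dY.t();
  vec db = sum(dY, 1);
  // dA = sum_k W_k * shift_{-k}(dY); shift_{-k} of dY is block (8 - k) of
  // dY's im2col stack since the offset table is symmetric under negation.
  mat dYcat = im2col9(dY, n, batch);
  const uword cout = dY.n_rows;
  mat dA(cin, A.n_cols, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    dA += Wcat.rows(k * cin, (k + 1) * cin - 1) *
      dYcat.rows((8 - k) * cout, (9 - k) * cout - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dWcat,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dA") = dA);
}
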