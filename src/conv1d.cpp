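// 1D convolution (cross-correlation) kernels for the spectral CNN.
// Layout convention matches R arrays (column-major):
//   X: cube(L, C_in, B)      batch of B spectra with C_in channels
//   W: cube(K, C_in, C_out)  filter bank
//   out: cube(L_out, C_out, B)
// im2col per sample: col(t, c*K + k) = Xpad(t*stride + k, c), so that
// vectorise(W.slice(o)) lines up with the col columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const arma::mat& x, int K, int stride, int pad,
                   arma::mat& col) {
  const int L = x.n_rows, Cin = x.n_cols;
  const int Lout = (L - K + 2 * pad) / stride + 1;
  col.zeros(Lout, K * Cin);
  for (int c = 0; c < Cin; ++c) {
    for (int k = 0; k < K; ++k) {
      const int j = c * K + k;
      for (int t = 0; t < Lout; ++t) {
        const int src = t * stride + k - pad;
        if (src >= 0 && src < L) col(t, j) = x(src, c);
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::cube& W,
                      const arma::vec& bias, int stride, int pad) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int K = W.n_rows, Cout = W.n_slices;
  if ((int)W.n_cols != Cin) stop("conv1d_fwd: channel mismatch");
  const int Lout = (L - K + 2 * pad) / stride + 1;
  if (Lout < 1) stop("conv1d_fwd: non-positive output length");

  arma::mat Wmat(K * Cin, Cout);
  for (int o = 0; o < Cout; ++o) Wmat.col(o) = arma::vectorise(W.slice(o));

  arma::cube out(Lout, Cout, B);
  arma::mat col;
  for (int n = 0; n < B; ++n) {
    im2col(X.slice(n), K, stride, pad, col);
    out.slice(n) = col * Wmat;
    out.slice(n).each_row() += bias.t();
  }
  return out;
}

// [[Rcpp::export]]
List conv1d_bwd(const arma::cube& X, const arma::cube& W,
                const arma::cube& dOut, int stride, int pad) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int K = W.n_rows, Cout = W.n_slices;
  const int Lout = dOut.n_rows;

  arma::mat Wmat(K * Cin, Cout);
  for (int o = 0; o < Cout; ++o) Wmat.col(o) = arma::vectorise(W.slice(o));

  arma::mat dWmat(K * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::cube dX(L, Cin, B, arma::fill::zeros);

  arma::mat col, dcol;
  for (int n = 0; n < B; ++n) {
    im2col(X.slice(n), K, stride, pad, col);
    dWmat += col.t() * dOut.slice(n);
    db += arma::sum(dOut.slice(n), 0).t();
    dcol = dOut.slice(n) * Wmat.t();   // Lout x K*Cin
    arma::mat& dx = dX.slice(n);
    for (int c = 0; c < Cin; ++c) {
      for (int k = 0; k < K; ++k) {
        const int j = c * K + k;
        for (int t = 0; t < Lout; ++t) {
          const int src = t * stride + k - pad;
          if (src >= 0 && src < L) dx(src, c) += dcol(t, j);
        }
      }
    }
  }

  arma::cube dW(K, Cin, Cout);
  for (int o = 0; o < Cout; ++o) {
    dW.slice(o) = arma::reshape(dWmat.col(o), K, Cin);
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
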