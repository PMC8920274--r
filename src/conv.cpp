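// Batched valid 1-D convolution over channel x position x sample arrays.
// Kernels are stored row-wise as nk x (C*w) with column-major vectorised
// windows, i.e. kernel row k dotted with vectorise(X.cols(j, j+w-1)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::mat& X, int w) {
  const int C = X.n_rows;
  const int Lout = X.n_cols - w + 1;
  arma::mat Xc(C * w, Lout);
  for (int j = 0; j < Lout; ++j)
    Xc.col(j) = arma::vectorise(X.cols(j, j + w - 1));
  return Xc;
}

// [[Rcpp::export(name = ".conv1dFwd")]]
arma::cube conv1dFwd(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b, int w) {
  const int B = X.n_slices;
  const int Lout = X.n_cols - w + 1;
  arma::cube Y(W.n_rows, Lout, B);
  for (int i = 0; i < B; ++i) {
    Y.slice(i) = W * im2col(X.slice(i), w);
    Y.slice(i).each_col() += b;
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1dBwd")]]
List conv1dBwd(const arma::cube& X, const arma::mat& W,
               const arma::cube& dY, int w) {
  const int B = X.n_slices;
  const int C = X.n_rows;
  const int Lout = dY.n_cols;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(W.n_rows, arma::fill::zeros);
  arma::cube dX(C, X.n_cols, B, arma::fill::zeros);
  for (int i = 0; i < B; ++i) {
    arma::mat Xc = im2col(X.slice(i), w);
    dW += dY.slice(i) * Xc.t();
    db += arma::sum(dY.slice(i), 1);
    arma::mat dXc = W.t() * dY.slice(i);   // (C*w) x Lout
    for (int j = 0; j < Lout; ++j) {
      dX.slice(i).cols(j, j + w - 1) +=
        arma::reshape(dXc.col(j), C, w);
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Global max over positions, restricted per sample to columns
// [start_i, end_i] (0-based, inclusive). Returns maxima and argmax
// positions (1-based, for R-side gradient routing).
// [[Rcpp::export(name = ".maxPoolFwd")]]
List maxPoolFwd(const arma::cube& Y, const arma::ivec& start,
                const arma::ivec& end) {
  const int B = Y.n_slices;
  const int nk = Y.n_rows;
  arma::mat M(nk, B);
  arma::imat A(nk, B);
  for (int i = 0; i < B; ++i) {
    const arma::mat sub = Y.slice(i).cols(start[i], end[i]);
    arma::uword idx;
    for (int k = 0; k < nk; ++k) {
      M(k, i) = sub.row(k).max(idx);
      A(k, i) = start[i] + (int)idx + 1;
    }
  }
  return List::create(_["max"] = M, _["argmax"] = A);
}
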