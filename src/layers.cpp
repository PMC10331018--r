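// Compiled kernels for the slice feature extractor. Layout contract (see
// R/nn-layers.R): a batch of N slices with C channels on an H x W grid is a
// (H*W*N) x C matrix, pixels column-major within a slice, slices stacked.
// Convolution gathers 3x3 neighbourhoods by a precomputed 1-based index
// matrix IDX (n x 9) whose out-of-image entries point to row n+1 (zero pad).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".cppConvFwd")]]
List cppConvFwd(const arma::mat& X, const arma::mat& W,
                const arma::vec& b, const arma::umat& IDX, bool keepCols) {
  const arma::uword n = X.n_rows, Cin = X.n_cols;
  arma::mat cols(n, 9 * Cin);
  for (arma::uword o = 0; o < 9; ++o) {
    for (arma::uword c = 0; c < Cin; ++c) {
      double* dst = cols.colptr(o * Cin + c);
      const double* src = X.colptr(c);
      const arma::uword* idx = IDX.colptr(o);
      for (arma::uword i = 0; i < n; ++i) {
        arma::uword j = idx[i] - 1;          // 1-based; n means zero pad
        dst[i] = (j < n) ? src[j] : 0.0;
      }
    }
  }
  arma::mat Y = cols * W;
  Y.each_row() += b.t();
  if (keepCols) return List::create(_["Y"] = Y, _["cols"] = cols);
  return List::create(_["Y"] = Y);
}

// [[Rcpp::export(name = ".cppConvBwd")]]
List cppConvBwd(const arma::mat& dY, const arma::mat& cols,
                const arma::mat& W, const arma::umat& IDX) {
  const arma::uword n = dY.n_rows;
  const arma::uword Cin = W.n_rows / 9;
  arma::mat dW = cols.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dcols = dY * W.t();
  arma::mat dX(n, Cin, arma::fill::zeros);
  for (arma::uword o = 0; o < 9; ++o) {
    for (arma::uword c = 0; c < Cin; ++c) {
      double* dst = dX.colptr(c);
      const double* src = dcols.colptr(o * Cin + c);
      const arma::uword* idx = IDX.colptr(o);
      for (arma::uword i = 0; i < n; ++i) {
        arma::uword j = idx[i] - 1;
        if (j < n) dst[j] += src[i];
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".cppPoolFwd")]]
List cppPoolFwd(const arma::mat& X, const arma::uvec& i1, const arma::uvec& i2,
                const arma::uvec& i3, const arma::uvec& i4, bool keepArg) {
  const arma::uword m = i1.n_elem, C = X.n_cols;
  arma::mat Y(m, C);
  IntegerMatrix arg(keepArg ? m : 0, keepArg ? C : 0);
  for (arma::uword c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    for (arma::uword i = 0; i < m; ++i) {
      double v1 = x[i1[i] - 1], v2 = x[i2[i] - 1];
      double v3 = x[i3[i] - 1], v4 = x[i4[i] - 1];
      double best = v1; int which = 1;
      if (v2 > best) { best = v2; which = 2; }
      if (v3 > best) { best = v3; which = 3; }
      if (v4 > best) { best = v4; which = 4; }
      y[i] = best;
      if (keepArg) arg(i, c) = which;
    }
  }
  if (keepArg) return List::create(_["Y"] = Y, _["arg"] = arg);
  return List::create(_["Y"] = Y);
}

// [[Rcpp::export(name = ".cppPoolBwd")]]
arma::mat cppPoolBwd(const arma::mat& dY, const IntegerMatrix& arg,
                     const arma::uvec& i1, const arma::uvec& i2,
                     const arma::uvec& i3, const arma::uvec& i4,
                     int inRows) {
  const arma::uword m = dY.n_rows, C = dY.n_cols;
  arma::mat dX(inRows, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    double* dst = dX.colptr(c);
    const double* g = dY.colptr(c);
    for (arma::uword i = 0; i < m; ++i) {
      arma::uword j;
      switch (arg(i, c)) {
        case 1: j = i1[i] - 1; break;
        case 2: j = i2[i] - 1; break;
        case 3: j = i3[i] - 1; break;
        default: j = i4[i] - 1; break;
      }
      dst[j] += g[i];
    }
  }
  return dX;
}

// [[Rcpp::export(name = ".cppBnFwdTrain")]]
List cppBnFwdTrain(const arma::mat& X, const arma::vec& gamma,
                   const arma::vec& beta, double eps) {
  const arma::uword n = X.n_rows, C = X.n_cols;
  arma::rowvec mu = arma::mean(X, 0);
  arma::rowvec v(C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double acc = 0.0, m = mu[c];
    for (arma::uword i = 0; i < n; ++i) { double d = x[i] - m; acc += d * d; }
    v[c] = acc / n;
  }
  arma::rowvec invstd = 1.0 / arma::sqrt(v + eps);
  arma::mat xhat = X;
  xhat.each_row() -= mu;
  xhat.each_row() %= invstd;
  arma::mat Y = xhat;
  Y.each_row() %= gamma.t();
  Y.each_row() += beta.t();
  return List::create(_["Y"] = Y, _["xhat"] = xhat,
                      _["invstd"] = invstd.t(), _["mu"] = mu.t(),
                      _["v"] = v.t());
}

// [[Rcpp::export(name = ".cppBnFwdEval")]]
arma::mat cppBnFwdEval(const arma::mat& X, const arma::vec& scale,
                       const arma::vec& shift) {
  arma::mat Y = X;
  Y.each_row() %= scale.t();
  Y.each_row() += shift.t();
  return Y;
}

// [[Rcpp::export(name = ".cppBnBwd")]]
List cppBnBwd(const arma::mat& dY, const arma::mat& xhat,
              const arma::vec& invstd, const arma::vec& gamma) {
  const arma::uword n = dY.n_rows;
  arma::rowvec dgamma = arma::sum(dY % xhat, 0);
  arma::rowvec dbeta = arma::sum(dY, 0);
  arma::mat dxhat = dY;
  dxhat.each_row() %= gamma.t();
  arma::rowvec m1 = arma::mean(dxhat, 0);
  arma::rowvec m2 = arma::mean(dxhat % xhat, 0);
  arma::mat dX = dxhat;
  dX.each_row() -= m1;
  dX -= xhat.each_row() % m2;
  dX.each_row() %= invstd.t();
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma.t(),
                      _["dbeta"] = dbeta.t());
}

// [[Rcpp::export(name = ".cppRelu")]]
arma::mat cppRelu(const arma::mat& X) {
  arma::mat Y = X;
  Y.for_each([](double& v) { if (v < 0) v = 0; });
  return Y;
}

// [[Rcpp::export(name = ".cppReluBwd")]]
arma::mat cppReluBwd(const arma::mat& dY, const arma::mat& pre) {
  arma::mat dX = dY;
  const double* p = pre.memptr();
  double* d = dX.memptr();
  const arma::uword nn = dX.n_elem;
  for (arma::uword i = 0; i < nn; ++i) if (p[i] <= 0) d[i] = 0;
  return dX;
}
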