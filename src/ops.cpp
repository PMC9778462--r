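// Convolution and activation kernels for the network engine.
//
// Feature volumes are (C, H, W) arrays with the channel index fastest,
// mapped onto arma::cube as (rows = C, cols = H, slices = W). Weights are
// stored flattened as (c_out x c_in*k*k), matching the patch-row ordering
// produced by im2col below; the ordering is internal to these kernels.
// The R-level im2col/col2im in autograd.R implement the same lowering and
// serve as an independent oracle in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col_cpp(const arma::cube& x, int k, int stride, int pad,
                            int& Ho, int& Wo) {
  const int C = x.n_rows, H = x.n_cols, W = x.n_slices;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  Ho = (Hp - k) / stride + 1;
  Wo = (Wp - k) / stride + 1;
  arma::mat cols(C * k * k, Ho * Wo, arma::fill::zeros);
  for (int b = 0; b < k; ++b) {
    for (int a = 0; a < k; ++a) {
      const int r0 = (b * k + a) * C;
      for (int j = 0; j < Wo; ++j) {
        const int wj = j * stride + b - pad;
        if (wj < 0 || wj >= W) continue;
        for (int i = 0; i < Ho; ++i) {
          const int hi = i * stride + a - pad;
          if (hi < 0 || hi >= H) continue;
          std::memcpy(cols.colptr(j * Ho + i) + r0,
                      x.slice_colptr(wj, hi), C * sizeof(double));
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int k, int stride, int pad) {
  int Ho, Wo;
  arma::mat cols = im2col_cpp(x, k, stride, pad, Ho, Wo);
  arma::mat y = W * cols;
  y.each_col() += b;
  return arma::cube(y.memptr(), W.n_rows, Ho, Wo);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& W,
                  const arma::cube& dy, int k, int stride, int pad) {
  const int C = x.n_rows, H = x.n_cols, Wd = x.n_slices;
  int Ho, Wo;
  arma::mat cols = im2col_cpp(x, k, stride, pad, Ho, Wo);
  const arma::mat gm(const_cast<double*>(dy.memptr()), dy.n_rows,
                     Ho * Wo, false, true);
  arma::mat dW = gm * cols.t();
  arma::vec db = arma::sum(gm, 1);
  arma::mat dcols = W.t() * gm;
  arma::cube dx(C, H, Wd, arma::fill::zeros);
  for (int b = 0; b < k; ++b) {
    for (int a = 0; a < k; ++a) {
      const int r0 = (b * k + a) * C;
      for (int j = 0; j < Wo; ++j) {
        const int wj = j * stride + b - pad;
        if (wj < 0 || wj >= Wd) continue;
        for (int i = 0; i < Ho; ++i) {
          const int hi = i * stride + a - pad;
          if (hi < 0 || hi >= H) continue;
          double* dst = dx.slice_colptr(wj, hi);
          const double* src = dcols.colptr(j * Ho + i) + r0;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dW") = dW,
                      Named("db") = db);
}

// [[Rcpp::export]]
NumericVector cpp_elu_fwd(NumericVector x) {
  NumericVector v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    v[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  v.attr("dim") = x.attr("dim");
  return v;
}

// dELU from the forward value: 1 where v > 0, v + 1 elsewhere.
// [[Rcpp::export]]
NumericVector cpp_elu_bwd(NumericVector v, NumericVector g) {
  NumericVector d(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i)
    d[i] = v[i] > 0 ? g[i] : g[i] * (v[i] + 1.0);
  d.attr("dim") = g.attr("dim");
  return d;
}
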