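// Single-precision gather/GEMM primitives behind the network engine.
//
// A convolution layer is expressed as: gather shifted copies of the
// (pixels x channels) activation matrix into an im2col block matrix,
// then one GEMM against the (taps*channels x out-channels) weight
// matrix. The same three primitives (gather+GEMM, gather+crossprod,
// GEMM+scatter) also cover the transposed-convolution phases and the
// whole backward pass. Arithmetic is float32 — the standard precision
// for CNN training — which roughly doubles BLAS throughput; interfaces
// stay double on the R side.
//
// Index vectors are 1-based row indices; 0 marks a zero-padding source
// (gathers write zeros, scatters skip).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static fmat to_f(const mat& x) { return conv_to<fmat>::from(x); }

// Gather rows of X (with 0 => zero row) for one tap.
static void gather_block(const fmat& X, const Rcpp::IntegerVector& idx,
                         fmat& cols, uword col0) {
  const uword n = idx.size(), C = X.n_cols;
  for (uword c = 0; c < C; ++c) {
    const float* xc = X.colptr(c);
    float* oc = cols.colptr(col0 + c);
    for (uword i = 0; i < n; ++i) {
      const int j = idx[i];
      oc[i] = j ? xc[j - 1] : 0.0f;
    }
  }
}

static fmat build_cols(const fmat& Xf, const Rcpp::List& idx) {
  const uword taps = idx.size(), C = Xf.n_cols;
  fmat cols(Rcpp::as<Rcpp::IntegerVector>(idx[0]).size(), taps * C);
  for (uword o = 0; o < taps; ++o)
    gather_block(Xf, idx[o], cols, o * C);
  return cols;
}

// out = [gathered cols of X] %*% W + b (b recycled over rows)
// [[Rcpp::export]]
arma::mat gemm_gather(const arma::mat& X, const Rcpp::List& idx,
                      const arma::mat& W, const arma::vec& b) {
  fmat cols = build_cols(to_f(X), idx);
  fmat out = cols * to_f(W);
  frowvec bf = conv_to<frowvec>::from(b);
  out.each_row() += bf;
  return conv_to<mat>::from(out);
}

// t([gathered cols of X]) %*% dout  — the weight gradient
// [[Rcpp::export]]
arma::mat crossprod_gather(const arma::mat& X, const Rcpp::List& idx,
                           const arma::mat& dout) {
  fmat cols = build_cols(to_f(X), idx);
  fmat dw = cols.t() * to_f(dout);
  return conv_to<mat>::from(dw);
}

// Scatter-add (dout %*% t(W)) tap blocks back onto an N-row matrix:
// the activation gradient.
// [[Rcpp::export]]
arma::mat mm_scatter(const arma::mat& dout, const Rcpp::List& idx,
                     const arma::mat& W, const int nrow_out) {
  fmat dcols = to_f(dout) * to_f(W).t();
  const uword taps = idx.size(), C = dcols.n_cols / taps;
  fmat dX(nrow_out, C, fill::zeros);
  for (uword o = 0; o < taps; ++o) {
    Rcpp::IntegerVector ix = idx[o];
    const uword n = ix.size();
    for (uword c = 0; c < C; ++c) {
      const float* sc = dcols.colptr(o * C + c);
      float* tc = dX.colptr(c);
      for (uword i = 0; i < n; ++i) {
        const int j = ix[i];
        if (j) tc[j - 1] += sc[i];
      }
    }
  }
  return conv_to<mat>::from(dX);
}
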