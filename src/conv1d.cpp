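// Batched 1D convolution kernels for the temporal-attention detector.
// Layout: signals are cubes [channels, T, batch]; kernels are cubes
// [out_channels, in_channels, taps] with explicit integer time offsets per
// tap (output at t reads input at t + offset, zero outside the window).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& X, const arma::cube& W,
                          const arma::vec& b, const arma::ivec& offs) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword Cout = W.n_rows, K = W.n_slices;
  if (W.n_cols != C) Rcpp::stop("channel mismatch in conv1d_fwd");
  cube Y(Cout, T, B);
  for (uword s = 0; s < B; ++s) Y.slice(s) = repmat(b, 1, T);
  for (uword j = 0; j < K; ++j) {
    const sword o = offs[j];
    const sword t_lo = std::max((sword)0, -o);
    const sword t_hi = std::min((sword)T - 1, (sword)T - 1 - o);
    if (t_lo > t_hi) continue;
    const mat Wj = W.slice(j);
    for (uword s = 0; s < B; ++s) {
      Y.slice(s).cols(t_lo, t_hi) += Wj * X.slice(s).cols(t_lo + o, t_hi + o);
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::cube& dY, const arma::cube& X,
                          const arma::cube& W, const arma::ivec& offs) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword K = W.n_slices;
  cube dX(C, T, B, fill::zeros);
  cube dW(W.n_rows, W.n_cols, K, fill::zeros);
  vec db(W.n_rows, fill::zeros);
  for (uword j = 0; j < K; ++j) {
    const sword o = offs[j];
    const sword t_lo = std::max((sword)0, -o);
    const sword t_hi = std::min((sword)T - 1, (sword)T - 1 - o);
    if (t_lo > t_hi) continue;
    const mat Wjt = W.slice(j).t();
    mat acc(W.n_rows, W.n_cols, fill::zeros);
    for (uword s = 0; s < B; ++s) {
      const mat dYs = dY.slice(s).cols(t_lo, t_hi);
      acc += dYs * X.slice(s).cols(t_lo + o, t_hi + o).t();
      dX.slice(s).cols(t_lo + o, t_hi + o) += Wjt * dYs;
    }
    dW.slice(j) = acc;
  }
  for (uword s = 0; s < B; ++s) db += sum(dY.slice(s), 1);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
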