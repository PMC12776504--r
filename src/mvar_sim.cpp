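#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

//' MVAR recursion (internal)
//'
//' Runs x_t = sum_r A_r x_{t-r} + e_t over pre-drawn innovations.
//' Innovations are generated in R so that the R RNG stream governs
//' reproducibility; this routine is deterministic given its inputs.
//'
//' @param coefs R x (R*p) matrix, the horizontal concatenation [A_1 ... A_p].
//' @param innov R x (burnin + n) innovation matrix.
//' @param burnin number of leading samples to discard.
//' @return R x n simulated series.
//' @keywords internal
// [[Rcpp::export(name = ".mvar_recurse")]]
arma::mat mvar_recurse(const arma::mat& coefs, const arma::mat& innov, int burnin) {
  const int R = innov.n_rows;
  const int total = innov.n_cols;
  const int p = coefs.n_cols / R;
  arma::mat x(R, total, arma::fill::zeros);
  for (int t = 0; t < total; ++t) {
    arma::vec acc = innov.col(t);
    const int lags = std::min(t, p);
    for (int r = 1; r <= lags; ++r) {
      acc += coefs.cols((r - 1) * R, r * R - 1) * x.col(t - r);
    }
    x.col(t) = acc;
  }
  return x.cols(burnin, total - 1);
}
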