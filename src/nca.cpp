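// Fast inner loop for diagonal-metric NCA feature weighting.
// Pairwise absolute differences are stored once for the n*(n-1)/2 unordered
// pairs (the weighted city-block distance is symmetric), so each gradient
// iteration costs two matrix-vector products against that pair matrix.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".nca_fit_cpp")]]
Rcpp::NumericVector nca_fit_cpp(const arma::mat& X, const arma::umat& same,
                                double sigma, double lambda, int iters,
                                double lr) {
  const uword n = X.n_rows, p = X.n_cols;
  const uword m = n * (n - 1) / 2;
  mat A(m, p);
  uvec pi_idx(m), pj_idx(m);
  uword t = 0;
  for (uword j = 1; j < n; ++j) {
    for (uword i = 0; i < j; ++i) {
      A.row(t) = abs(X.row(i) - X.row(j));
      pi_idx(t) = i;
      pj_idx(t) = j;
      ++t;
    }
  }
  vec w = ones<vec>(p);
  mat K(n, n), P(n, n), C(n, n);
  vec du(m), bu(m), pi_i(n), rs(n);
  for (int it = 0; it < iters; ++it) {
    vec w2 = square(w);
    du = A * w2;
    K.zeros();
    for (uword s = 0; s < m; ++s) {
      double v = std::exp(-du(s) / sigma);
      K(pi_idx(s), pj_idx(s)) = v;
      K(pj_idx(s), pi_idx(s)) = v;
    }
    rs = sum(K, 1) + 1e-300;
    P = K.each_col() / rs;
    pi_i = sum(P % conv_to<mat>::from(same), 1);
    C = P % (repmat(pi_i, 1, n) - conv_to<mat>::from(same));
    for (uword s = 0; s < m; ++s)
      bu(s) = C(pi_idx(s), pj_idx(s)) + C(pj_idx(s), pi_idx(s));
    vec g = A.t() * bu;
    w += lr * ((2.0 / sigma) * (w % g) - 2.0 * lambda * w);
  }
  return Rcpp::wrap(w);
}
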