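// Matrix-exponential propagation kernel for continuous-time Markov schemes.
// Occupancies are row vectors; p(t + dt) = p(t) * expm(Q * dt).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double dt) {
  return arma::expmat(Q * dt);
}

// Propagate p0 through n equal steps of length dt at a fixed voltage.
// Returns an (n + 1) x k matrix whose first row is p0. The inner loop is
// written out by hand: k is small (9 or 13 states) and the generic
// matrix-vector product's temporaries dominate otherwise.
// [[Rcpp::export]]
NumericMatrix cpp_propagate_fixed(const arma::mat& Q, const arma::rowvec& p0,
                                  double dt, int n) {
  const arma::mat E = arma::expmat(Q * dt);
  const int k = p0.n_elem;
  NumericMatrix out(n + 1, k);
  std::vector<double> cur(p0.begin(), p0.end()), nxt(k);
  const double* e = E.memptr();  // column-major k x k
  for (int j = 0; j < k; ++j) out(0, j) = cur[j];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      const double* ecol = e + j * k;
      double acc = 0.0;
      for (int m = 0; m < k; ++m) acc += cur[m] * ecol[m];
      nxt[j] = acc;
    }
    cur.swap(nxt);
    for (int j = 0; j < k; ++j) out(i + 1, j) = cur[j];
  }
  return out;
}

// Single jump over an arbitrary duration (no intermediate sampling).
// [[Rcpp::export]]
arma::rowvec cpp_jump(const arma::mat& Q, const arma::rowvec& p0, double dur) {
  return p0 * arma::expmat(Q * dur);
}
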