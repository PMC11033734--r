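#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Minimum, over all k-column subsets S of M, of the smallest singular value
// of M[, S].  Smallest singular value is computed as sqrt(lambda_min) of the
// k x k Gram matrix of the subset, which for k <= 8 is much cheaper than an
// SVD of the submatrix.  Subsets are enumerated in colex order with an
// iterative odometer; no recursion, no allocation inside the loop.
//
// early_exit: if > 0, return as soon as the running minimum drops below this
// value (used by the random search to discard candidates that cannot beat the
// incumbent).  A negative value disables the shortcut.
// [[Rcpp::export(name = ".sin_enum_cpp")]]
double sin_enum_cpp(const arma::mat& M, int k, double early_exit = -1.0) {
  const int n = M.n_cols;
  if (k < 1 || k > n) stop("subset size out of range");

  arma::mat G = M.t() * M;  // n x n Gram, subsets index into it

  arma::uvec idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;

  arma::mat Gs(k, k);
  arma::vec ev(k);
  double best = std::numeric_limits<double>::infinity();

  while (true) {
    // lambda_min of G[idx, idx]
    for (int a = 0; a < k; ++a)
      for (int b = 0; b <= a; ++b) {
        Gs(a, b) = G(idx[a], idx[b]);
        Gs(b, a) = Gs(a, b);
      }
    arma::eig_sym(ev, Gs);
    double lam = ev[0];
    // numerical-rank floor: eigenvalues below round-off relative to the
    // Gram scale are exact zeros (for integer-valued matrices any genuine
    // nonzero eigenvalue is orders of magnitude larger)
    double scale = arma::trace(Gs);
    if (lam < 1e-12 * std::max(1.0, scale)) lam = 0;
    if (lam < best) {
      best = lam;
      if (early_exit >= 0 && best <= early_exit * early_exit) break;
    }

    // next combination (odometer)
    int pos = k - 1;
    while (pos >= 0 && (int)idx[pos] == n - k + pos) --pos;
    if (pos < 0) break;
    ++idx[pos];
    for (int j = pos + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  }
  return std::sqrt(best);
}
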