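#include <Rcpp.h>
using namespace Rcpp;

// Propagate the exact discrete-time update z[n+1] = Phi z[n] + eta[, n] of a
// linear SDE (Ornstein-Uhlenbeck form).  `eta` holds the pre-generated,
// already-correlated Gaussian innovations (d x n).  Returns the full state
// path as an (n+1) x d matrix including the initial state.
// [[Rcpp::export]]
NumericMatrix propagate_lti(NumericMatrix phi, NumericVector z0,
                            NumericMatrix eta) {
  const int d = phi.nrow();
  const int n = eta.ncol();
  if (phi.ncol() != d || z0.size() != d || eta.nrow() != d)
    stop("dimension mismatch in propagate_lti");
  NumericMatrix out(n + 1, d);
  std::vector<double> z(z0.begin(), z0.end()), znew(d);
  for (int j = 0; j < d; ++j) out(0, j) = z[j];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) {
      double acc = eta(j, i);
      for (int k = 0; k < d; ++k) acc += phi(j, k) * z[k];
      znew[j] = acc;
    }
    for (int j = 0; j < d; ++j) {
      z[j] = znew[j];
      out(i + 1, j) = z[j];
    }
  }
  return out;
}
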