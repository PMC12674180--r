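// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with explicit initial state.
// a[0] is assumed 1 (normalized by the caller).
// [[Rcpp::export(name = ".cpp_iir")]]
NumericVector cpp_iir(const arma::vec &b, const arma::vec &a,
                      const NumericVector &x, const arma::vec &zi) {
  const int n = x.size(), m = zi.n_elem;
  NumericVector y(n);
  arma::vec z = zi;
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (m > 0 ? z[0] : 0.0);
    for (int k = 0; k < m - 1; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    if (m > 0) z[m - 1] = b[m] * xi - a[m] * yi;
    y[i] = yi;
  }
  return y;
}
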