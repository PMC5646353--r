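#include <Rcpp.h>
using namespace Rcpp;

// MVAR recursion x_t = sum_k A_k x_{t-k} + e_t with zero initial state.
// `coef` holds [A_1 A_2 ... A_p] side by side (m x m*p); `innov` is the
// m x n innovation matrix. Returns the m x n signal matrix.
// [[Rcpp::export(name = ".mvar_recurse")]]
NumericMatrix mvar_recurse(NumericMatrix coef, NumericMatrix innov) {
  const int m = innov.nrow(), n = innov.ncol();
  if (coef.nrow() != m || coef.ncol() % m != 0)
    stop("coefficient block has incompatible shape");
  const int p = coef.ncol() / m;
  NumericMatrix x(m, n);
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < m; ++i) x(i, t) = innov(i, t);
    const int kmax = t < p ? t : p;
    for (int k = 1; k <= kmax; ++k) {
      const int off = (k - 1) * m;
      for (int i = 0; i < m; ++i) {
        double acc = 0.0;
        for (int j = 0; j < m; ++j) acc += coef(i, off + j) * x(j, t - k);
        x(i, t) += acc;
      }
    }
  }
  return x;
}
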