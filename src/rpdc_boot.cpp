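// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// One full bootstrap null draw chain for the RPDC significance test:
// residual-resampled simulation from the null coefficient block, MVAR refit
// at fixed order, and the band-mean renormalized-PDC statistic of the
// tested pair. Returns `n_boot` draws. Uses the R RNG (seed-reproducible).
//
// coef:  m x m*p null coefficient block [A_1 ... A_p] (tested entry zeroed)
// res:   m x N fitted residual matrix (columns = time)
// i, j:  1-based receiver / sender of the tested pair
// omk:   p x nf matrix of omega * k values (2 pi f k / fs)
// [[Rcpp::export(name = ".rpdc_boot_null")]]
NumericVector rpdc_boot_null(const arma::mat& coef, const arma::mat& res,
                             int n, int burn, int p, int i, int j,
                             const arma::mat& omk, int n_boot) {
  const int m = res.n_rows;
  const int N = res.n_cols;
  const int nf = omk.n_cols;
  const int ii = i - 1, jj = j - 1;
  const arma::mat cosM = arma::cos(omk);
  const arma::mat sinM = arma::sin(omk);
  NumericVector out(n_boot);
  arma::mat x(m, n + burn);
  for (int b = 0; b < n_boot; ++b) {
    // residual resampling (R RNG for reproducibility via set.seed)
    for (int t = 0; t < n + burn; ++t) {
      int idx = (int)(unif_rand() * N);
      if (idx >= N) idx = N - 1;
      for (int r = 0; r < m; ++r) x(r, t) = res(r, idx);
    }
    // MVAR recursion in place
    for (int t = 0; t < n + burn; ++t) {
      const int kmax = t < p ? t : p;
      for (int k = 1; k <= kmax; ++k) {
        const int off = (k - 1) * m;
        for (int r = 0; r < m; ++r) {
          double acc = 0.0;
          for (int c = 0; c < m; ++c) acc += coef(r, off + c) * x(c, t - k);
          x(r, t) += acc;
        }
      }
    }
    const arma::mat xs = x.cols(burn, n + burn - 1);
    // least-squares refit at order p
    const int rows = n - p;
    arma::mat Y = xs.cols(p, n - 1).t();
    arma::mat Z(rows, m * p);
    for (int k = 1; k <= p; ++k)
      Z.cols((k - 1) * m, k * m - 1) = xs.cols(p - k, n - 1 - k).t();
    arma::mat ZtZ = Z.t() * Z;
    arma::mat B = arma::solve(ZtZ, Z.t() * Y, arma::solve_opts::likely_sympd);
    arma::vec resid_i = Y.col(ii) - Z * B.col(ii);
    double sig_ii = arma::dot(resid_i, resid_i) /
      std::max(rows - m * p, 1);
    arma::mat G = arma::inv_sympd(ZtZ);
    arma::vec a(p);
    arma::mat Gsub(p, p);
    for (int k = 0; k < p; ++k) {
      a(k) = B(k * m + jj, ii);
      for (int l = 0; l < p; ++l) Gsub(k, l) = G(k * m + jj, l * m + jj);
    }
    arma::mat Cov = sig_ii * Gsub;
    arma::mat Qc = Cov * cosM, Qs = Cov * sinM;
    double acc = 0.0;
    for (int f = 0; f < nf; ++f) {
      double V11 = arma::dot(cosM.col(f), Qc.col(f));
      double V22 = arma::dot(sinM.col(f), Qs.col(f));
      double V12 = -arma::dot(cosM.col(f), Qs.col(f));
      double Z1 = -arma::dot(a, cosM.col(f));
      double Z2 = arma::dot(a, sinM.col(f));
      double tr = V11 + V22;
      double det = V11 * V22 - V12 * V12;
      double lam;
      if (det > 1e-12 * tr * tr)
        lam = (Z1 * Z1 * V22 - 2.0 * Z1 * Z2 * V12 + Z2 * Z2 * V11) / det;
      else
        lam = (Z1 * Z1 * V11 + 2.0 * Z1 * Z2 * V12 + Z2 * Z2 * V22) /
          (tr * tr);
      acc += lam;
    }
    out[b] = acc / nf;
  }
  return out;
}
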