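// Blockwise Gaussian-kernel reductions.
//
// Computes S = sum_{i,j} exp(-||a_i - b_j||^2 / (2 sigma^2)) and, when
// requested, dS/dA and dS/dB, visiting (row-block x row-block) tiles so the
// largest temporary is block_size^2 — never nrow(A) * nrow(B). This is the
// streaming evaluation path; the naive R path in losses.R serves as its
// reference implementation in the tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".kernel_sums_cpp")]]
Rcpp::List kernel_sums_cpp(const arma::mat& A, const arma::mat& B,
                           double sigma, int block_size, bool grad) {
  const arma::uword n1 = A.n_rows, n2 = B.n_rows;
  const arma::uword bs = block_size < 1 ? 1 : (arma::uword)block_size;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double invs2 = 1.0 / (sigma * sigma);

  arma::vec ra = arma::sum(arma::square(A), 1);
  arma::vec rb = arma::sum(arma::square(B), 1);

  double s = 0.0;
  arma::mat dA, dB;
  if (grad) {
    dA.zeros(n1, A.n_cols);
    dB.zeros(n2, B.n_cols);
  }

  for (arma::uword i0 = 0; i0 < n1; i0 += bs) {
    const arma::uword i1 = std::min(i0 + bs, n1) - 1;
    const arma::mat Ab = A.rows(i0, i1);
    const arma::vec rab = ra.subvec(i0, i1);
    for (arma::uword j0 = 0; j0 < n2; j0 += bs) {
      const arma::uword j1 = std::min(j0 + bs, n2) - 1;
      const arma::mat Bb = B.rows(j0, j1);
      arma::mat K = -2.0 * (Ab * Bb.t());
      K.each_col() += rab;
      K.each_row() += rb.subvec(j0, j1).t();
      K.transform([inv2s2](double d2) {
        return std::exp(-(d2 > 0.0 ? d2 : 0.0) * inv2s2);
      });
      s += arma::accu(K);
      if (grad) {
        const arma::vec rs = arma::sum(K, 1);
        const arma::rowvec cs = arma::sum(K, 0);
        dA.rows(i0, i1) -= invs2 * (Ab.each_col() % rs - K * Bb);
        dB.rows(j0, j1) -= invs2 * (Bb.each_col() % cs.t() - K.t() * Ab);
      }
    }
  }
  if (grad) {
    return Rcpp::List::create(Rcpp::Named("sum") = s,
                              Rcpp::Named("dA") = dA,
                              Rcpp::Named("dB") = dB);
  }
  return Rcpp::List::create(Rcpp::Named("sum") = s);
}
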