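// Hot path for the variability statistic: angular cosine distances between
// binary cell vectors, Gower double-centering of squared distances, spectral
// decomposition, and mean distance to the centroid over the retained
// (positive-eigenvalue) principal coordinates.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Returns -1 when fewer than 3 cells have a nonzero restriction (the caller
// raises the typed condition).
// [[Rcpp::export]]
double dispersion_value_cpp(const arma::mat& X, const double eig_tol) {
  const arma::uvec keep = arma::find(arma::sum(X, 1) > 0);
  if (keep.n_elem < 3) return -1.0;
  arma::mat Xs = X.rows(keep);
  const arma::uword n = Xs.n_rows;

  arma::mat C = Xs * Xs.t();
  arma::vec d = C.diag();
  arma::mat cs = C / arma::sqrt(d * d.t());
  cs.clamp(-1.0, 1.0);
  arma::mat D2 = arma::acos(cs) / (arma::datum::pi / 2.0);
  D2.diag().zeros();
  D2 = arma::square(D2);

  const arma::vec rm = arma::mean(D2, 1);
  const double mm = arma::mean(rm);
  arma::mat B = -0.5 * (D2 - arma::repmat(rm, 1, n) - arma::repmat(rm.t(), n, 1) + mm);

  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, B)) Rcpp::stop("eigendecomposition failed");
  const double emax = eval.max();
  if (emax <= 0.0) return 0.0;
  const arma::uvec pos = arma::find(eval > eig_tol * emax);
  if (pos.n_elem == 0) return 0.0;
  arma::vec norms2 = arma::square(evec.cols(pos)) * eval.elem(pos);
  return arma::mean(arma::sqrt(norms2));
}
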