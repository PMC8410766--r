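// Compiled pseudo-Voigt mixture model and analytic Jacobian used by the
// nonlinear least-squares fitting routines.  Parameters are packed per
// peak as (center, amplitude, fwhh, eta).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".pv_profile")]]
arma::vec pv_profile(const arma::vec& par, const arma::vec& x) {
  const int k = par.n_elem / 4;
  const double a = 4.0 * std::log(2.0);
  arma::vec y(x.n_elem, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const double c = par(4 * j), A = par(4 * j + 1);
    const double f = par(4 * j + 2), e = par(4 * j + 3);
    for (arma::uword i = 0; i < x.n_elem; ++i) {
      const double u = (x(i) - c) / f;
      const double L = 1.0 / (1.0 + 4.0 * u * u);
      const double G = std::exp(-a * u * u);
      y(i) += A * (e * L + (1.0 - e) * G);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".pv_jacobian")]]
arma::mat pv_jacobian(const arma::vec& par, const arma::vec& x) {
  const int k = par.n_elem / 4;
  const double a = 4.0 * std::log(2.0);
  arma::mat J(x.n_elem, par.n_elem);
  for (int j = 0; j < k; ++j) {
    const double c = par(4 * j), A = par(4 * j + 1);
    const double f = par(4 * j + 2), e = par(4 * j + 3);
    for (arma::uword i = 0; i < x.n_elem; ++i) {
      const double u = (x(i) - c) / f;
      const double L = 1.0 / (1.0 + 4.0 * u * u);
      const double G = std::exp(-a * u * u);
      const double dLdu = -8.0 * u * L * L;
      const double dGdu = -2.0 * a * u * G;
      const double mix = e * dLdu + (1.0 - e) * dGdu;
      J(i, 4 * j) = A * mix * (-1.0 / f);
      J(i, 4 * j + 1) = e * L + (1.0 - e) * G;
      J(i, 4 * j + 2) = A * mix * (-u / f);
      J(i, 4 * j + 3) = A * (L - G);
    }
  }
  return J;
}
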