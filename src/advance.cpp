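// Core cohort-advancement step.
//
// Within one (year, age) cell the transition rates are frozen, so the
// four-compartment system (M, S, E, L) is a linear ODE with constant
// coefficients.  We augment it with three absorbing accumulators
// (other-cause deaths, lung-cancer deaths, cumulative incident cases) and
// take the matrix exponential of the 7x7 generator: the step is then exact
// for piecewise-constant rates and unconditionally nonnegative.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Augmented generator for one cell.  State ordering:
// 0 M never-smokers, 1 S smokers, 2 E ex-smokers, 3 L lung-cancer patients,
// 4 cumulative other-cause deaths, 5 cumulative lung-cancer deaths,
// 6 cumulative incident cases (counter, not a person compartment).
static mat cell_generator_aug(double sigma, double delta, double lambda,
                              double mu, double nu,
                              double kS, double kE, double qS, double qE) {
  mat G(7, 7, fill::zeros);
  // never-smokers
  G(0, 0) = -(mu + sigma + lambda);
  G(1, 0) = sigma;
  G(3, 0) = lambda;
  G(4, 0) = mu;
  G(6, 0) = lambda;
  // current smokers
  G(1, 1) = -((1.0 + qS) * mu + delta + kS * lambda);
  G(2, 1) = delta;
  G(3, 1) = kS * lambda;
  G(4, 1) = (1.0 + qS) * mu;
  G(6, 1) = kS * lambda;
  // ex-smokers
  G(2, 2) = -((1.0 + qE) * mu + kE * lambda);
  G(3, 2) = kE * lambda;
  G(4, 2) = (1.0 + qE) * mu;
  G(6, 2) = kE * lambda;
  // lung-cancer patients: baseline other-cause mortality plus excess nu
  G(3, 3) = -(mu + nu);
  G(4, 3) = mu;
  G(5, 3) = nu;
  return G;
}

//' Matrix exponential (Pade scaling-and-squaring)
//'
//' @param A square numeric matrix
//' @return exp(A)
//' @keywords internal
// [[Rcpp::export(name = ".expm_cpp")]]
arma::mat expm_cpp(const arma::mat& A) {
  return expmat(A);
}

// Advance every age cohort of one calendar year by dt.
//
// state: 4 x n matrix (rows M, S, E, L), columns are ages.
// sigma, delta, lambda, mu, nu: length-n per-age rates for this year.
// Returns a 7 x n matrix: rows 1-4 the state after dt, rows 5-7 the
// other-cause deaths, cancer deaths and new cases that occurred in the cell.
// [[Rcpp::export(name = ".advance_cohorts_cpp")]]
arma::mat advance_cohorts_cpp(const arma::mat& state,
                              const arma::vec& sigma, const arma::vec& delta,
                              const arma::vec& lambda, const arma::vec& mu,
                              const arma::vec& nu,
                              double kS, double kE, double qS, double qE,
                              double dt) {
  const uword n = state.n_cols;
  if (state.n_rows != 4)
    Rcpp::stop("state must have 4 rows (M, S, E, L)");
  if (sigma.n_elem != n || delta.n_elem != n || lambda.n_elem != n ||
      mu.n_elem != n || nu.n_elem != n)
    Rcpp::stop("rate vectors must match the number of age columns");

  mat out(7, n, fill::zeros);
  vec x(7, fill::zeros);
  for (uword j = 0; j < n; ++j) {
    mat G = cell_generator_aug(sigma(j), delta(j), lambda(j), mu(j), nu(j),
                               kS, kE, qS, qE);
    mat P = expmat(G * dt);
    x.zeros();
    x.subvec(0, 3) = state.col(j);
    out.col(j) = P * x;
  }
  return out;
}
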