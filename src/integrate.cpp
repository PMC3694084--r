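// Local-linearization integrator for the neural-mass state equations.
// Mirrors the R reference implementation (state_derivative, system_jacobian,
// ll_step) on the same population-major state layout; the R path is kept as
// the cross-checked reference and this is the default engine.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static vec sigm(const vec& v, double r, double eta, double s0) {
  return 1.0 / (1.0 + exp(-r * (v - eta))) - s0;
}

static vec dsigm(const vec& v, double r, double eta) {
  vec e = exp(-r * (v - eta));
  return r * e / square(1.0 + e);
}

// [[Rcpp::export]]
arma::mat ll_integrate_cpp(const Rcpp::List& model, const arma::vec& u,
                           const arma::vec& grid, bool full_state) {
  const int n = Rcpp::as<int>(model["n"]);
  const vec He = Rcpp::as<vec>(model["He"]);
  const vec Hi = Rcpp::as<vec>(model["Hi"]);
  const vec Te = Rcpp::as<vec>(model["Te"]);
  const vec Ti = Rcpp::as<vec>(model["Ti"]);
  const vec g = Rcpp::as<vec>(model["g"]);
  const double r = Rcpp::as<double>(model["r"]);
  const double eta = Rcpp::as<double>(model["eta"]);
  const vec CU = Rcpp::as<vec>(model["CU"]);
  const mat M4 = Rcpp::as<mat>(model["M4"]);
  const mat M5 = Rcpp::as<mat>(model["M5"]);
  const mat M8 = Rcpp::as<mat>(model["M8"]);
  const double s0 = 1.0 / (1.0 + std::exp(r * eta));
  const int d = 9 * n;
  const int T = grid.n_elem;

  auto B = [n](int k) { return span((k - 1) * n, k * n - 1); };

  vec x(d, fill::zeros);
  mat X(full_state ? d : n, T, fill::zeros);
  vec f(d);
  mat J(d, d);

  for (int t = 0; t + 1 < T; ++t) {
    const double dt = grid[t + 1] - grid[t];
    const vec S9 = sigm(x(B(9)), r, eta, s0);
    const vec S1 = sigm(x(B(1)), r, eta, s0);
    const vec S7 = sigm(x(B(7)), r, eta, s0);

    f.zeros();
    f(B(1)) = x(B(4));
    f(B(2)) = x(B(5));
    f(B(3)) = x(B(6));
    f(B(7)) = x(B(8));
    f(B(4)) = (He % (M4 * S9 + CU * u[t]) - 2.0 * x(B(4)) - x(B(1)) / Te) / Te;
    f(B(5)) = (He % (M5 * S9 + g[1] * S1) - 2.0 * x(B(5)) - x(B(2)) / Te) / Te;
    f(B(6)) = (Hi * g[3] % S7 - 2.0 * x(B(6)) - x(B(3)) / Ti) / Ti;
    f(B(8)) = (He % (M8 * S9) - 2.0 * x(B(8)) - x(B(7)) / Te) / Te;
    f(B(9)) = x(B(5)) - x(B(6));

    const vec d9 = dsigm(x(B(9)), r, eta);
    const vec d1 = dsigm(x(B(1)), r, eta);
    const vec d7 = dsigm(x(B(7)), r, eta);

    J.zeros();
    J(B(1), B(4)) = eye(n, n);
    J(B(2), B(5)) = eye(n, n);
    J(B(3), B(6)) = eye(n, n);
    J(B(7), B(8)) = eye(n, n);
    const mat De = diagmat(He / Te);
    J(B(4), B(9)) = De * M4 * diagmat(d9);
    J(B(4), B(1)) = diagmat(-1.0 / square(Te));
    J(B(4), B(4)) = diagmat(-2.0 / Te);
    J(B(5), B(9)) = De * M5 * diagmat(d9);
    J(B(5), B(1)) = diagmat(He % d1 * g[1] / Te);
    J(B(5), B(2)) = diagmat(-1.0 / square(Te));
    J(B(5), B(5)) = diagmat(-2.0 / Te);
    J(B(6), B(7)) = diagmat(Hi % d7 * g[3] / Ti);
    J(B(6), B(3)) = diagmat(-1.0 / square(Ti));
    J(B(6), B(6)) = diagmat(-2.0 / Ti);
    J(B(8), B(9)) = De * M8 * diagmat(d9);
    J(B(8), B(7)) = diagmat(-1.0 / square(Te));
    J(B(8), B(8)) = diagmat(-2.0 / Te);
    J(B(9), B(5)) = eye(n, n);
    J(B(9), B(6)) = -eye(n, n);

    // local-linearization update (expm(dt J) - I) J^- f evaluated through
    // the augmented exponential: the top-right block of expm(dt [J f; 0 0])
    // is the integral of expm(s J) f over the step, which coincides with the
    // explicit pseudo-inverse form whenever f is dynamically consistent —
    // here it always is (the 9-state layout's conserved mode keeps f in the
    // range of J), and the augmented form stays exact for singular J
    mat M(d + 1, d + 1, fill::zeros);
    M(span(0, d - 1), span(0, d - 1)) = J * dt;
    M(span(0, d - 1), d) = f * dt;
    const mat E = expmat(M);
    x += E(span(0, d - 1), d);
    if (!x.is_finite())
      Rcpp::stop("state integration diverged at time index %d (t = %g ms)",
                 t + 2, grid[t + 1]);
    if (full_state) X.col(t + 1) = x;
    else X.col(t + 1) = x(B(9));
  }
  return X;
}
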