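// Regularized-Stokeslet kernels: dense mobility assembly and velocity
// evaluation. The 2D regularized Stokeslet for the blob
//   phi_eps(r) = 2 eps^4 / (pi (r^2 + eps^2)^3)
// gives the velocity contribution of a point force f at distance d = x - xk:
//   u = (1 / 8 pi mu) [ (2 eps^2/R - ln R - 1) f + 2 (f . d) d / R ],
//   R = r^2 + eps^2,
// obtained by solving mu Lap(u) = grad p - f phi_eps with div u = 0
// (G = (ln R - eps^2/R)/4pi, r B' = r^2 (ln R - 1)/8pi). The kernel is
// exactly divergence-free, regular at r = 0, and reduces to the classical
// 2D Stokeslet as eps -> 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat rs_mobility_matrix(const arma::mat& xk, double mu, double eps) {
  const arma::uword M = xk.n_rows;
  arma::mat A(2 * M, 2 * M);
  const double pref = 1.0 / (8.0 * M_PI * mu);
  const double e2 = eps * eps;
  for (arma::uword i = 0; i < M; ++i) {
    for (arma::uword j = 0; j < M; ++j) {
      const double dx = xk(i, 0) - xk(j, 0);
      const double dy = xk(i, 1) - xk(j, 1);
      const double r2e = dx * dx + dy * dy + e2;
      const double a = 2.0 * e2 / r2e - std::log(r2e) - 1.0;
      const double b = 2.0 / r2e;
      // u_i = pref * [ a I + b d d^T ] f_j ; unknowns ordered (fx_1..fx_M, fy_1..fy_M)
      A(i, j)         = pref * (a + b * dx * dx);
      A(i, j + M)     = pref * (b * dx * dy);
      A(i + M, j)     = pref * (b * dy * dx);
      A(i + M, j + M) = pref * (a + b * dy * dy);
    }
  }
  return A;
}

// [[Rcpp::export]]
arma::mat rs_velocity(const arma::mat& pts, const arma::mat& xk,
                      const arma::mat& fk, double mu, double eps) {
  const arma::uword n = pts.n_rows, M = xk.n_rows;
  arma::mat u(n, 2, arma::fill::zeros);
  const double pref = 1.0 / (8.0 * M_PI * mu);
  const double e2 = eps * eps;
  for (arma::uword i = 0; i < n; ++i) {
    double ux = 0.0, uy = 0.0;
    const double px = pts(i, 0), py = pts(i, 1);
    for (arma::uword k = 0; k < M; ++k) {
      const double dx = px - xk(k, 0);
      const double dy = py - xk(k, 1);
      const double r2e = dx * dx + dy * dy + e2;
      const double a = 2.0 * e2 / r2e - std::log(r2e) - 1.0;
      const double fd = 2.0 * (fk(k, 0) * dx + fk(k, 1) * dy) / r2e;
      ux += a * fk(k, 0) + fd * dx;
      uy += a * fk(k, 1) + fd * dy;
    }
    u(i, 0) = pref * ux;
    u(i, 1) = pref * uy;
  }
  return u;
}

// Direct dense solve of the mobility system with iterative refinement.
// Returns forces (M x 2); the caller asserts the residual contract.
// [[Rcpp::export]]
arma::mat rs_solve_forces(const arma::mat& xk, const arma::mat& uk,
                          double mu, double eps, int refine) {
  const arma::uword M = xk.n_rows;
  arma::mat A = rs_mobility_matrix(xk, mu, eps);
  arma::vec b(2 * M);
  b.subvec(0, M - 1) = uk.col(0);
  b.subvec(M, 2 * M - 1) = uk.col(1);
  arma::vec f = arma::solve(A, b, arma::solve_opts::no_approx);
  for (int it = 0; it < refine; ++it) {
    arma::vec r = b - A * f;
    f += arma::solve(A, r, arma::solve_opts::no_approx);
  }
  arma::mat out(M, 2);
  out.col(0) = f.subvec(0, M - 1);
  out.col(1) = f.subvec(M, 2 * M - 1);
  return out;
}
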