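// Explicit transport kernels on the cell-masked grid.
//
// Field matrices are N_i x N_j with row index i along x (column 1 = vessel
// edge) and column index j along y. `open` flags interstitial nodes; nodes
// inside cells are impermeable obstacles: they are never updated and are
// omitted from the diffusion stencil and from upwind differences, so no mass
// ever crosses a cell boundary except through explicit uptake terms.

#include <Rcpp.h>
using namespace Rcpp;

// Masked 4-stencil diffusion, forward Euler, dimensionally split:
// an explicit x-sweep followed by an explicit y-sweep, each omitting
// stencil points inside cells. coef = D * dt / h^2; each 1D sweep is
// stable (and satisfies the maximum principle) for coef <= 1/2, which is
// what admits the model's standard stability number 0.375. Both sweeps
// exchange mass in symmetric pairs, so interstitial mass is conserved
// exactly under reflecting outer boundaries.
// dirichlet_left / dirichlet_right hold the edge columns fixed (their values
// are boundary data); when false the edge reflects (no-flux), as do the top
// and bottom rows and any in-cell neighbor.
// [[Rcpp::export]]
void diffuse_masked_inplace(NumericMatrix f, NumericMatrix buf,
                            LogicalMatrix open, double coef,
                            bool dirichlet_left, bool dirichlet_right) {
  const int ni = f.nrow(), nj = f.ncol();
  // x-sweep
  for (int j = 0; j < nj; ++j) {
    for (int i = 0; i < ni; ++i) {
      if (!open(i, j)) { buf(i, j) = f(i, j); continue; }
      if ((dirichlet_left && i == 0) || (dirichlet_right && i == ni - 1)) {
        buf(i, j) = f(i, j); continue;
      }
      const double c = f(i, j);
      double lap = 0.0;
      if (i > 0      && open(i - 1, j)) lap += f(i - 1, j) - c;
      if (i < ni - 1 && open(i + 1, j)) lap += f(i + 1, j) - c;
      buf(i, j) = c + coef * lap;
    }
  }
  std::copy(buf.begin(), buf.end(), f.begin());
  // y-sweep
  for (int j = 0; j < nj; ++j) {
    for (int i = 0; i < ni; ++i) {
      if (!open(i, j)) { buf(i, j) = f(i, j); continue; }
      if ((dirichlet_left && i == 0) || (dirichlet_right && i == ni - 1)) {
        buf(i, j) = f(i, j); continue;
      }
      const double c = f(i, j);
      double lap = 0.0;
      if (j > 0      && open(i, j - 1)) lap += f(i, j - 1) - c;
      if (j < nj - 1 && open(i, j + 1)) lap += f(i, j + 1) - c;
      buf(i, j) = c + coef * lap;
    }
  }
  std::copy(buf.begin(), buf.end(), f.begin());
}

// First-order upwind advection along a frozen velocity field. dtdh = dt / h.
// A masked or out-of-domain upwind neighbor contributes a zero gradient
// (velocities vanish on cell boundaries, so no flux enters cell interiors).
// [[Rcpp::export]]
void advect_upwind_inplace(NumericMatrix f, NumericMatrix buf,
                           NumericMatrix ux, NumericMatrix uy,
                           LogicalMatrix open, double dtdh,
                           bool dirichlet_left, bool dirichlet_right) {
  const int ni = f.nrow(), nj = f.ncol();
  for (int j = 0; j < nj; ++j) {
    for (int i = 0; i < ni; ++i) {
      if (!open(i, j)) { buf(i, j) = f(i, j); continue; }
      if ((dirichlet_left && i == 0) || (dirichlet_right && i == ni - 1)) {
        buf(i, j) = f(i, j); continue;
      }
      const double c = f(i, j);
      const double vx = ux(i, j), vy = uy(i, j);
      double adv = 0.0;
      if (vx > 0) {
        const double w = (i > 0 && open(i - 1, j)) ? f(i - 1, j) : c;
        adv += vx * (c - w);
      } else if (vx < 0) {
        const double e = (i < ni - 1 && open(i + 1, j)) ? f(i + 1, j) : c;
        adv += vx * (e - c);
      }
      if (vy > 0) {
        const double s = (j > 0 && open(i, j - 1)) ? f(i, j - 1) : c;
        adv += vy * (c - s);
      } else if (vy < 0) {
        const double n = (j < nj - 1 && open(i, j + 1)) ? f(i, j + 1) : c;
        adv += vy * (n - c);
      }
      buf(i, j) = c - dtdh * adv;
    }
  }
  std::copy(buf.begin(), buf.end(), f.begin());
}

// Receptor-localized oxygen uptake: at nodes covered by k live pseudo-
// receptors the sink is k * psi(xi, gamma), where psi is proportional to
// gamma under severe hypoxia (gamma < gamma_hyp / 2) and otherwise takes the
// sensitizer-tiered constant gamma0 * psi_tier. Returns the number of
// negativity clamps.
// `severe_slope` is the proportionality constant of the severe-hypoxia
// branch (rate = severe_slope * gamma below gamma_hyp / 2).
// [[Rcpp::export]]
int oxygen_uptake_inplace(NumericMatrix gamma, NumericMatrix xi,
                          IntegerMatrix count, double gamma0,
                          double gamma_hyp, NumericVector xi_breaks,
                          NumericVector psi, double dt, double severe_slope) {
  const int n = gamma.size();
  int clamps = 0;
  for (int idx = 0; idx < n; ++idx) {
    const int k = count[idx];
    if (k == 0) continue;
    const double g = gamma[idx];
    double rate;
    if (g < 0.5 * gamma_hyp) {
      rate = severe_slope * g;
    } else {
      const double x = xi[idx];
      double p;
      if      (x < xi_breaks[0]) p = psi[0];
      else if (x < xi_breaks[1]) p = psi[1];
      else if (x < xi_breaks[2]) p = psi[2];
      else                       p = psi[3];
      rate = gamma0 * p;
    }
    double v = g - dt * rate * k;
    if (v < 0) { v = 0.0; ++clamps; }
    gamma[idx] = v;
  }
  return clamps;
}

// Hypoxia-gated pro-drug activation: where gamma <= gamma_hyp, the fraction
// `frac` of local inactive drug converts to active drug (exact mass
// transfer, node by node).
// [[Rcpp::export]]
void activation_inplace(NumericMatrix eta_i, NumericMatrix eta_a,
                        NumericMatrix gamma, LogicalMatrix open,
                        double gamma_hyp, double frac) {
  const int n = eta_i.size();
  for (int idx = 0; idx < n; ++idx) {
    if (!open[idx]) continue;
    if (gamma[idx] <= gamma_hyp) {
      const double moved = frac * eta_i[idx];
      eta_i[idx] -= moved;
      eta_a[idx] += moved;
    }
  }
}

// Receptor-localized uptake of the active drug by live cells.
// `cell_nodes` holds, per cell, the 0-based linear node indices covered by
// its receptors (repeated with multiplicity); `count` is their tabulation
// over live cells. Per-cell accumulation increments (dt * alpha * sum of
// pre-uptake eta_a over the cell's receptor nodes) are returned; the same
// flux, k-fold at k-covered nodes, is removed from the field.
// [[Rcpp::export]]
NumericVector drug_uptake_inplace(NumericMatrix eta_a, IntegerMatrix count,
                                  List cell_nodes, LogicalVector alive,
                                  double alpha, double dt) {
  const int ncell = cell_nodes.size();
  NumericVector inc(ncell);
  for (int l = 0; l < ncell; ++l) {
    if (!alive[l]) continue;
    IntegerVector nodes = cell_nodes[l];
    double s = 0.0;
    for (int m = 0; m < nodes.size(); ++m) s += eta_a[nodes[m]];
    inc[l] = dt * alpha * s;
  }
  const int n = eta_a.size();
  for (int idx = 0; idx < n; ++idx) {
    const int k = count[idx];
    if (k == 0) continue;
    double v = eta_a[idx] * (1.0 - dt * alpha * k);
    if (v < 0) v = 0.0;
    eta_a[idx] = v;
  }
  return inc;
}
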