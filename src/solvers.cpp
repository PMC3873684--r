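#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system (a: sub, b: diag, c: super).
// Overwrites d with the solution. All vectors length n.
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d) {
  const int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// One-layer Crank-Nicolson diffusion solver on C(x,t):
//   dC/dt = D d2C/dx2,  C(0,t) = C0 (donor-face concentration K*Cv),
//   C(L,t) = 0 (sink), C(x,0) = 0.
// Uniform grid of n_nodes nodes (n_nodes-1 intervals). Time steps start at
// the diffusion-number limit nu_max*dx^2/D and grow geometrically as
// `growth` * elapsed time once the start-up boundary layer is resolved.
// Returns the concentration field and cumulative boundary fluxes (per unit
// area) at the requested output times.
// [[Rcpp::export]]
List cn_onelayer_cpp(double L, double D, double C0, NumericVector times,
                     int n_nodes = 2001, double growth = 0.01,
                     double nu_max = 5.0) {
  const int N = n_nodes - 1;          // intervals
  const double dx = L / N;
  const double g = D / dx;            // conductance per unit concentration
  const double dt_diff = nu_max * dx * dx / D;
  const int n_out = times.size();
  const int n_unk = N - 1;            // interior nodes

  std::vector<double> u(n_unk, 0.0);
  NumericMatrix C_out(n_out, n_nodes);
  NumericVector Qin(n_out), Qout(n_out), x(n_nodes);
  for (int j = 0; j < n_nodes; ++j) x[j] = j * dx;

  double t = 0.0, qin = 0.0, qout = 0.0;
  double f_in = g * (C0 - u[0]);      // instantaneous boundary fluxes
  double f_out = g * u[n_unk - 1];

  std::vector<double> a(n_unk), b(n_unk), c(n_unk), d(n_unk);
  const long max_steps = 100000000L;
  long steps = 0;

  for (int k = 0; k < n_out; ++k) {
    const double T = times[k];
    while (t < T) {
      double dt = std::max(dt_diff, growth * t);
      if (t + dt > T) dt = T - t;
      if (dt <= 0) break;
      const double r = D * dt / (2.0 * dx * dx);
      for (int i = 0; i < n_unk; ++i) {
        a[i] = -r; b[i] = 1.0 + 2.0 * r; c[i] = -r;
        double um = (i == 0) ? C0 : u[i - 1];
        double up = (i == n_unk - 1) ? 0.0 : u[i + 1];
        d[i] = u[i] + r * (um - 2.0 * u[i] + up);
      }
      d[0] += r * C0;                 // Dirichlet donor at the new level
      thomas(a, b, c, d);
      double f_in_new = g * (C0 - d[0]);
      double f_out_new = g * d[n_unk - 1];
      qin += 0.5 * (f_in + f_in_new) * dt;
      qout += 0.5 * (f_out + f_out_new) * dt;
      f_in = f_in_new; f_out = f_out_new;
      u = d;
      t += dt;
      if (++steps > max_steps) stop("cn_onelayer_cpp: step limit exceeded");
    }
    C_out(k, 0) = (T > 0.0) ? C0 : 0.0;
    for (int i = 0; i < n_unk; ++i) C_out(k, i + 1) = u[i];
    C_out(k, n_nodes - 1) = 0.0;
    Qin[k] = qin; Qout[k] = qout;
  }
  return List::create(_["x"] = x, _["times"] = times, _["C"] = C_out,
                      _["Q_in"] = Qin, _["Q_out"] = Qout);
}

// Two-layer (stratum corneum over viable epidermis/dermis) Crank-Nicolson
// solver. Works on the chemical-potential-like variable u = C/K, which is
// continuous across the interface under the equal-chemical-potential
// partition condition C_sc/K_sc = C_ved/K_ved; flux continuity
// D_sc K_sc du/dx = D_ved K_ved du/dx is built into the finite-volume
// interface node. Boundary conditions: u(0,t) = Cv (i.e. C_sc = K_sc*Cv),
// u(L_tot,t) = 0 (sink), u(x,0) = 0.
//
// n_per is the number of intervals per layer; the interface node is shared.
// Returns fields C(x, t_k) (concentration, already multiplied by the layer
// K), cumulative boundary fluxes per unit area and the stored mass per
// area at the requested times.
// [[Rcpp::export]]
List cn_bilayer_cpp(double Lsc, double Lved, double Ksc, double Kved,
                    double Dsc, double Dved, double Cv, NumericVector times,
                    int n_per = 201, double growth = 0.01,
                    double nu_max = 5.0) {
  const int n1 = n_per, n2 = n_per;          // intervals per layer
  const double dx1 = Lsc / n1, dx2 = Lved / n2;
  const double g1 = Ksc * Dsc / dx1;         // face conductances (per u)
  const double g2 = Kved * Dved / dx2;
  const int n_nodes = n1 + n2 + 1;           // incl. both Dirichlet ends
  const int n_unk = n_nodes - 2;
  const int ib = n1 - 1;                     // interface index in unknowns
  const double dt_diff = std::min(nu_max * dx1 * dx1 / Dsc,
                                  nu_max * dx2 * dx2 / Dved);
  const int n_out = times.size();

  // node "capacity" (mass per unit u per unit area)
  std::vector<double> m(n_unk), gl(n_unk), gr(n_unk);
  for (int i = 0; i < n_unk; ++i) {
    if (i < ib)      { m[i] = Ksc * dx1;  gl[i] = g1; gr[i] = g1; }
    else if (i == ib){ m[i] = 0.5 * (Ksc * dx1 + Kved * dx2);
                       gl[i] = g1; gr[i] = g2; }
    else             { m[i] = Kved * dx2; gl[i] = g2; gr[i] = g2; }
  }

  NumericVector x(n_nodes);
  for (int j = 0; j <= n1; ++j) x[j] = j * dx1;
  for (int j = 1; j <= n2; ++j) x[n1 + j] = Lsc + j * dx2;

  std::vector<double> u(n_unk, 0.0);
  NumericMatrix C_out(n_out, n_nodes);
  NumericVector Qin(n_out), Qout(n_out), stored(n_out);

  double t = 0.0, qin = 0.0, qout = 0.0;
  double f_in = g1 * (Cv - u[0]);
  double f_out = g2 * u[n_unk - 1];

  std::vector<double> a(n_unk), b(n_unk), c(n_unk), d(n_unk);
  const long max_steps = 100000000L;
  long steps = 0;

  for (int k = 0; k < n_out; ++k) {
    const double T = times[k];
    while (t < T) {
      double dt = std::max(dt_diff, growth * t);
      if (t + dt > T) dt = T - t;
      if (dt <= 0) break;
      for (int i = 0; i < n_unk; ++i) {
        const double mi_dt = m[i] / dt;
        a[i] = -0.5 * gl[i];
        b[i] = mi_dt + 0.5 * (gl[i] + gr[i]);
        c[i] = -0.5 * gr[i];
        double um = (i == 0) ? Cv : u[i - 1];
        double up = (i == n_unk - 1) ? 0.0 : u[i + 1];
        d[i] = mi_dt * u[i]
             + 0.5 * (gl[i] * (um - u[i]) + gr[i] * (up - u[i]));
      }
      d[0] += 0.5 * gl[0] * Cv;    // donor Dirichlet at the new time level
      thomas(a, b, c, d);
      double f_in_new = g1 * (Cv - d[0]);
      double f_out_new = g2 * d[n_unk - 1];
      qin += 0.5 * (f_in + f_in_new) * dt;
      qout += 0.5 * (f_out + f_out_new) * dt;
      f_in = f_in_new; f_out = f_out_new;
      u = d;
      t += dt;
      if (++steps > max_steps) stop("cn_bilayer_cpp: step limit exceeded");
    }
    // record: convert potential back to concentration per layer
    C_out(k, 0) = (T > 0.0) ? Ksc * Cv : 0.0;
    for (int i = 0; i < n_unk; ++i) {
      double Khere = (i < ib) ? Ksc : (i > ib ? Kved : Ksc); // SC side at b
      C_out(k, i + 1) = Khere * u[i];
    }
    C_out(k, n_nodes - 1) = 0.0;
    double s = 0.0;
    for (int i = 0; i < n_unk; ++i) s += m[i] * u[i];
    Qin[k] = qin; Qout[k] = qout; stored[k] = s;
  }
  return List::create(_["x"] = x, _["times"] = times, _["C"] = C_out,
                      _["Q_in"] = Qin, _["Q_out"] = Qout,
                      _["stored"] = stored, _["interface_index"] = n1 + 1);
}
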