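// Hill-function ODE right-hand side, adaptive Dormand-Prince RK45
// integration on a fixed output grid, and the composite fitting
// objective (trajectory MSE + L1 parameter penalty + initial-condition
// penalty) evaluated for whole differential-evolution populations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// dx_i/dt = (-degc_i * x_i + H_i(x)) / tau, where
// H_i = (u_i + sum_{W_ji>0} W_ji x_j^3) /
//       (1 + u_i + sum_{W_ji>0} W_ji x_j^3 + sum_{W_ji<0} (-W_ji) x_j^3)
static void hill_rhs_c(const vec& x, const mat& W, const vec& u,
                       double tau, const vec& degc, vec& dx) {
  const int m = x.n_elem;
  vec x3 = x % x % x;
  for (int i = 0; i < m; ++i) {
    double num = u(i), rep = 0.0;
    for (int j = 0; j < m; ++j) {
      double w = W(j, i);
      if (w > 0) num += w * x3(j);
      else if (w < 0) rep -= w * x3(j);
    }
    double H = num / (1.0 + num + rep);
    dx(i) = (-degc(i) * x(i) + H) / tau;
  }
}

// [[Rcpp::export]]
arma::vec hill_rhs_cpp(const arma::vec& x, const arma::mat& W,
                       const arma::vec& u, double tau,
                       const arma::vec& degc) {
  if (tau <= 0) Rcpp::stop("tau must be > 0");
  vec dx(x.n_elem);
  hill_rhs_c(x, W, u, tau, degc, dx);
  return dx;
}

// Dormand-Prince 5(4) adaptive integration from tgrid[0] to tgrid[end],
// writing the state at every grid time into out (m x T). State is
// clamped to [0,1]^m after each accepted step (the model's invariant
// region; clamping only trims solver overshoot at the boundary).
// Returns false on step-count exhaustion or non-finite state.
static bool rk45_grid(const mat& W, const vec& u, double tau,
                      const vec& degc, const vec& x0, const vec& tgrid,
                      double rtol, double atol, int max_steps, mat& out) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                      e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                      e6 = 22.0 / 525, e7 = -1.0 / 40;
  const int m = x0.n_elem, T = tgrid.n_elem;
  vec x = clamp(x0, 0.0, 1.0);
  out.col(0) = x;
  vec k1(m), k2(m), k3(m), k4(m), k5(m), k6(m), k7(m), xt(m), xnew(m), err(m);
  double t = tgrid(0);
  double hmax = (tgrid(T - 1) - tgrid(0));
  double h = std::min(0.1 * tau, hmax > 0 ? hmax : 0.1 * tau);
  int steps = 0;
  hill_rhs_c(x, W, u, tau, degc, k1);
  for (int g = 1; g < T; ++g) {
    double tend = tgrid(g);
    while (t < tend) {
      if (++steps > max_steps) return false;
      if (t + h > tend) h = tend - t;
      xt = x + h * a21 * k1;
      hill_rhs_c(xt, W, u, tau, degc, k2);
      xt = x + h * (a31 * k1 + a32 * k2);
      hill_rhs_c(xt, W, u, tau, degc, k3);
      xt = x + h * (a41 * k1 + a42 * k2 + a43 * k3);
      hill_rhs_c(xt, W, u, tau, degc, k4);
      xt = x + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);
      hill_rhs_c(xt, W, u, tau, degc, k5);
      xt = x + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
      hill_rhs_c(xt, W, u, tau, degc, k6);
      xnew = x + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
      hill_rhs_c(xnew, W, u, tau, degc, k7);
      err = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
      double errnorm = 0.0;
      for (int i = 0; i < m; ++i) {
        double sc = atol + rtol * std::max(std::abs(x(i)), std::abs(xnew(i)));
        double r = err(i) / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / m);
      if (!std::isfinite(errnorm)) return false;
      if (errnorm <= 1.0) {
        t += h;
        x = clamp(xnew, 0.0, 1.0);
        hill_rhs_c(x, W, u, tau, degc, k1);  // FSAL invalidated by clamp
      }
      double fac = 0.9 * std::pow(errnorm > 1e-12 ? errnorm : 1e-12, -0.2);
      fac = std::min(5.0, std::max(0.2, fac));
      h *= fac;
      double hmin = 1e-12 * std::max(1.0, std::abs(tend));
      if (h < hmin) h = hmin;
    }
    out.col(g) = x;
    t = tend;
  }
  return out.is_finite();
}

// [[Rcpp::export]]
arma::mat hill_simulate_cpp(const arma::mat& W, const arma::vec& u,
                            double tau, const arma::vec& x0,
                            const arma::vec& tgrid, int kd_index, double k,
                            double rtol, double atol, int max_steps) {
  if (tau <= 0) Rcpp::stop("tau must be > 0");
  vec degc(x0.n_elem, fill::ones);
  if (kd_index >= 0) degc(kd_index) = 1.0 + k;
  mat out(x0.n_elem, tgrid.n_elem);
  if (!rk45_grid(W, u, tau, degc, x0, tgrid, rtol, atol, max_steps, out))
    Rcpp::stop("ODE solver failure (step limit %d exceeded or non-finite state; tau = %g)",
               max_steps, tau);
  return out;
}

// Composite loss for a population of decision vectors.
// theta layout: [w_e (E entries, one per edge), u (m), tau, x0 per branch
// (B blocks of m)]. Returns 4 x NP matrix: L_model, L_p, L_IC, L_total.
// Solver failure scores the member with `penalty`.
// [[Rcpp::export]]
arma::mat hill_loss_population_cpp(const arma::mat& theta,
                                   const arma::uvec& esrc,
                                   const arma::uvec& etgt, int m,
                                   const Rcpp::List& times_list,
                                   const Rcpp::List& values_list,
                                   double lambda_p, double lambda_ic,
                                   double rtol, double atol, int max_steps,
                                   double penalty) {
  const int E = esrc.n_elem, B = times_list.size(), NP = theta.n_cols;
  std::vector<vec> times(B);
  std::vector<mat> values(B);
  for (int b = 0; b < B; ++b) {
    times[b] = Rcpp::as<vec>(times_list[b]);
    values[b] = Rcpp::as<mat>(values_list[b]);
  }
  mat res(4, NP);
  vec degc(m, fill::ones);
  for (int p = 0; p < NP; ++p) {
    const vec th = theta.col(p);
    mat W(m, m, fill::zeros);
    for (int e = 0; e < E; ++e) W(esrc(e), etgt(e)) = th(e);
    vec u = th.subvec(E, E + m - 1);
    double tau = th(E + m);
    double Lmodel = 0.0, Lic = 0.0;
    bool ok = tau > 0;
    for (int b = 0; ok && b < B; ++b) {
      vec x0 = th.subvec(E + m + 1 + b * m, E + m + b * m + m);
      mat out(m, times[b].n_elem);
      ok = rk45_grid(W, u, tau, degc, x0, times[b], rtol, atol, max_steps, out);
      if (!ok) break;
      Lmodel += accu(square(values[b] - out));
      Lic += abs(values[b].col(0) - x0).max();
    }
    double Lp = accu(abs(th.subvec(0, E + m - 1))) + std::abs(tau);
    if (!ok) {
      res(0, p) = penalty; res(1, p) = Lp; res(2, p) = 0;
      res(3, p) = penalty;
    } else {
      res(0, p) = Lmodel; res(1, p) = Lp; res(2, p) = Lic;
      res(3, p) = Lmodel + lambda_p * Lp + lambda_ic * Lic;
    }
  }
  return res;
}
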