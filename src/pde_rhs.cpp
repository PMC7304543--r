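#include <Rcpp.h>
using namespace Rcpp;

// Method-of-lines right-hand side for the nondimensional cross-diffusion
// system. State layout: y = (p_1..p_n, q_1..q_n). Conservative face fluxes:
// the total-density gradient times the face-averaged population share,
// regularized by eps in the vacuum ahead of the front. The beta-CDF
// responses g(w), delta(w) are supplied as dense tables on a uniform w-grid
// over [0, 1] and interpolated linearly (table resolution is chosen in R so
// that the interpolation error is far below the discretization error;
// calling R::pbeta per cell per stage would dominate the runtime).

struct ResponseTab {
  const double *v;
  int n;
  double eval(double w) const {
    if (w <= 0.0) return v[0];
    if (w >= 1.0) return v[n - 1];
    const double t = w * (n - 1);
    const int i = static_cast<int>(t);
    const double f = t - i;
    return v[i] * (1.0 - f) + v[i + 1] * f;
  }
};

static void rhs_eval(const std::vector<double> &y, std::vector<double> &dy,
                     std::vector<double> &Fp, std::vector<double> &Fq,
                     int n, double dx, double rho_hat,
                     const ResponseTab &g_tab, const ResponseTab &d_tab,
                     double eps) {
  for (int i = 0; i < n - 1; ++i) {
    const double ui = y[i] + y[n + i];
    const double uj = y[i + 1] + y[n + i + 1];
    const double grad = (uj - ui) / dx;
    const double denom = ui + uj + eps;
    Fp[i] = (y[i] + y[i + 1]) / denom * grad;
    Fq[i] = (y[n + i] + y[n + i + 1]) / denom * grad;
  }
  for (int i = 0; i < n; ++i) {
    const double fin_p = (i < n - 1) ? Fp[i] : 0.0;
    const double fout_p = (i > 0) ? Fp[i - 1] : 0.0;
    const double fin_q = (i < n - 1) ? Fq[i] : 0.0;
    const double fout_q = (i > 0) ? Fq[i - 1] : 0.0;
    const double w = 1.0 - (y[i] + y[n + i]);
    const double birth = rho_hat * g_tab.eval(w) * y[i];
    const double death = d_tab.eval(w) * y[i];
    dy[i] = (fin_p - fout_p) / dx + birth - death;
    dy[n + i] = (fin_q - fout_q) / dx + death;
  }
}

// Classic RK4 march of the semi-discrete system, saving n_save equispaced
// snapshots (including the initial state); steps_per_save fixed sub-steps
// of size dt between consecutive snapshots.
// [[Rcpp::export(name = ".pde_integrate")]]
NumericMatrix pde_integrate(NumericVector y0, double dx, double dt,
                            int n_save, int steps_per_save, double rho_hat,
                            NumericVector g_values, NumericVector d_values,
                            double eps) {
  const int m = y0.size();
  const int n = m / 2;
  const ResponseTab g_tab = {g_values.begin(), (int)g_values.size()};
  const ResponseTab d_tab = {d_values.begin(), (int)d_values.size()};
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(m), k2(m), k3(m), k4(m), tmp(m);
  std::vector<double> Fp(n - 1), Fq(n - 1);
  NumericMatrix out(n_save, m);
  for (int j = 0; j < m; ++j) out(0, j) = y[j];
  for (int s = 1; s < n_save; ++s) {
    for (int step = 0; step < steps_per_save; ++step) {
      rhs_eval(y, k1, Fp, Fq, n, dx, rho_hat, g_tab, d_tab, eps);
      for (int j = 0; j < m; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
      rhs_eval(tmp, k2, Fp, Fq, n, dx, rho_hat, g_tab, d_tab, eps);
      for (int j = 0; j < m; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
      rhs_eval(tmp, k3, Fp, Fq, n, dx, rho_hat, g_tab, d_tab, eps);
      for (int j = 0; j < m; ++j) tmp[j] = y[j] + dt * k3[j];
      rhs_eval(tmp, k4, Fp, Fq, n, dx, rho_hat, g_tab, d_tab, eps);
      for (int j = 0; j < m; ++j)
        y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    }
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < m; ++j) out(s, j) = y[j];
  }
  return out;
}
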