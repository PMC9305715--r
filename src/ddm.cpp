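#include <Rcpp.h>
using namespace Rcpp;

// Conductance k = kappa * n^alpha; n^alpha goes through log space for very
// large n (cell-level populations reach 1e8) to avoid precision loss in pow.
static inline double conductance_cpp(double kappa, double alpha, double n) {
  if (n > 1e6) return kappa * std::exp(alpha * std::log(n));
  return kappa * std::pow(n, alpha);
}

// Positive root of A*Cf^2 + B*Cf - A*C*Km = 0 with A = k*C and
// B = A*(Km - C) + n*s*Vm (the F = U balance). The root is computed with the
// cancellation-stable q-formula: when B >= 0 the textbook (-B + sqrt(disc))
// subtracts nearly equal terms (n*s*Vm can exceed A*C by many orders of
// magnitude), so the conjugate form 2*A*C*Km / (B + sqrt(disc)) is used.
static inline double cf_root(double A, double nsVm, double C, double Km) {
  const double B = A * (Km - C) + nsVm;
  const double disc = B * B + 4.0 * A * A * C * Km;
  const double sq = std::sqrt(disc);
  if (B >= 0.0) return 2.0 * A * C * Km / (B + sq);
  return (sq - B) / (2.0 * A);
}

// [[Rcpp::export(name = ".ddm_sink_cf_cpp")]]
double ddm_sink_cf_cpp(double C, double n, double s, double kappa,
                       double alpha, double Vm, double Km) {
  const double A = conductance_cpp(kappa, alpha, n) * C;
  return cf_root(A, n * s * Vm, C, Km);
}

// Forward-Euler integration of individual dry mass for one population size.
// State vectors are reported at every node (steps + 1 values); Cf and U at
// the final node are diagnostic evaluations of the final state. cum_unloaded
// is the left-fold sum of U*dt over the steps actually taken, so that
// (s_end - s0) * n / (1 - r) == cum_unloaded up to roundoff.
// fail_step is -1 on success, otherwise the first step index at which the
// state became non-finite.
// [[Rcpp::export(name = ".ddm_euler_cpp")]]
List ddm_euler_cpp(double n, double s0, double C, double kappa, double alpha,
                   double Vm, double Km, double r, int steps, double dt) {
  NumericVector s(steps + 1), Cf(steps + 1), U(steps + 1);
  const double A = conductance_cpp(kappa, alpha, n) * C;
  double cum = 0.0;
  int fail = -1;
  double si = s0;
  for (int i = 0; i <= steps; ++i) {
    const double cfi = cf_root(A, n * si * Vm, C, Km);
    const double ui = n * si * Vm * cfi / (Km + cfi);
    s[i] = si;
    Cf[i] = cfi;
    U[i] = ui;
    if (!std::isfinite(si) || !std::isfinite(cfi) || !std::isfinite(ui)) {
      fail = i;
      break;
    }
    if (i < steps) {
      cum += ui * dt;
      si += dt * (1.0 - r) * ui / n;
    }
  }
  return List::create(_["s"] = s, _["Cf"] = Cf, _["U"] = U,
                      _["cum_unloaded"] = cum, _["fail_step"] = fail);
}

// Final dry mass for a vector of population sizes (one source concentration
// per n). NaN marks an integration failure for that n.
// [[Rcpp::export(name = ".ddm_final_dry_mass_cpp")]]
NumericVector ddm_final_dry_mass_cpp(NumericVector n, NumericVector C,
                                     double s0, double kappa, double alpha,
                                     double Vm, double Km, double r,
                                     int steps, double dt) {
  const int m = n.size();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double A = conductance_cpp(kappa, alpha, n[j]) * C[j];
    double si = s0;
    bool ok = true;
    for (int i = 0; i < steps; ++i) {
      const double cfi = cf_root(A, n[j] * si * Vm, C[j], Km);
      const double ui = n[j] * si * Vm * cfi / (Km + cfi);
      si += dt * (1.0 - r) * ui / n[j];
      if (!std::isfinite(si)) { ok = false; break; }
    }
    out[j] = ok ? si : NA_REAL;
  }
  return out;
}
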