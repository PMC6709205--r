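// Fixed-step RK4 integration of the single-compartment calcium/indicator
// model at the line-scan sampling interval. Action potentials enter as
// instantaneous calcium increments at the nearest sample index (the train is
// slow, ~20 ms between pulses, relative to the ~1.4 ms step).
//
//   dc/dt = -k_serca (c - c0) - k_pmca c + leak
//   db/dt = kon c^h (Btot - b) - koff b
//
// leak is fixed at cell construction (k_pmca_nominal * c0) so that with
// nominal rates the calcium equation reduces to -(k_serca + k_pmca)(c - c0),
// while blocking PMCA raises resting calcium and blocking SERCA does not.

#include <Rcpp.h>
#include <cmath>
#include <vector>

namespace {

struct Rhs {
  double ks, kp, c0, leak, kon, koff, btot, hill;
  inline double dc(double c) const { return -ks * (c - c0) - kp * c + leak; }
  inline double db(double c, double b) const {
    double ch = (hill == 1.0) ? c : std::pow(std::max(c, 0.0), hill);
    return kon * ch * (btot - b) - koff * b;
  }
};

}  // namespace

// RK4 integration of the indicator binding ODE along a sampled calcium
// trace, with calcium linearly interpolated at half steps.
// [[Rcpp::export(name = ".sim_b_cpp")]]
Rcpp::NumericVector sim_b_cpp(Rcpp::NumericVector ca, double dt,
                              Rcpp::NumericVector pars, double b_init) {
  Rhs f;
  f.ks = f.kp = f.c0 = f.leak = 0.0;
  f.kon = pars["indicator_kon"];
  f.koff = pars["indicator_koff"];
  f.btot = pars["indicator_total"];
  f.hill = pars["hill_n"];
  const int n = ca.size();
  Rcpp::NumericVector b(n);
  double bb = b_init;
  for (int i = 0; i < n; ++i) {
    b[i] = bb;
    if (i == n - 1) break;
    double c0 = ca[i], c1 = ca[i + 1], cm = 0.5 * (c0 + c1);
    double k1 = f.db(c0, bb);
    double k2 = f.db(cm, bb + 0.5 * dt * k1);
    double k3 = f.db(cm, bb + 0.5 * dt * k2);
    double k4 = f.db(c1, bb + dt * k3);
    bb += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  }
  return b;
}

// [[Rcpp::export(name = ".sim_rk4_cpp")]]
Rcpp::NumericMatrix sim_rk4_cpp(int n_samples, double dt,
                                Rcpp::NumericVector pars,
                                Rcpp::IntegerVector pulse_idx,
                                double pulse_amp,
                                double c_init, double b_init) {
  Rhs f;
  f.ks = pars["k_serca"];
  f.kp = pars["k_pmca"];
  f.c0 = pars["baseline_ca"];
  f.leak = pars["leak"];
  f.kon = pars["indicator_kon"];
  f.koff = pars["indicator_koff"];
  f.btot = pars["indicator_total"];
  f.hill = pars["hill_n"];

  std::vector<char> is_pulse(n_samples, 0);
  for (int i = 0; i < pulse_idx.size(); ++i) {
    int id = pulse_idx[i] - 1;  // 1-based from R
    if (id >= 0 && id < n_samples) is_pulse[id] = 1;
  }

  Rcpp::NumericMatrix out(n_samples, 2);
  double c = c_init, b = b_init;
  for (int i = 0; i < n_samples; ++i) {
    if (is_pulse[i]) c += pulse_amp;
    out(i, 0) = c;
    out(i, 1) = b;
    if (i == n_samples - 1) break;
    // classical RK4 for the coupled (c, b) system
    double k1c = f.dc(c),                      k1b = f.db(c, b);
    double k2c = f.dc(c + 0.5 * dt * k1c),     k2b = f.db(c + 0.5 * dt * k1c, b + 0.5 * dt * k1b);
    double k3c = f.dc(c + 0.5 * dt * k2c),     k3b = f.db(c + 0.5 * dt * k2c, b + 0.5 * dt * k2b);
    double k4c = f.dc(c + dt * k3c),           k4b = f.db(c + dt * k3c, b + dt * k3b);
    c += dt / 6.0 * (k1c + 2.0 * k2c + 2.0 * k3c + k4c);
    b += dt / 6.0 * (k1b + 2.0 * k2b + 2.0 * k3b + k4b);
  }
  return out;
}
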