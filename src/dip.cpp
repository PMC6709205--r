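// Hartigan & Hartigan dip statistic: the minimum over all unimodal
// distribution functions G (convex below the mode, concave above, with a
// single atom allowed at the mode) of sup_x |F_n(x) - G(x)|.
//
// For a mode placed at the m-th unique sample value, feasibility of a given
// sup-distance d decomposes into:
//  * convex side: the lower convex hull of the upper band points
//    (u_i, F(u_i^-) + d) must stay above the lower band (u_j, F(u_j) - d);
//  * concave side: mirror image with the upper concave hull;
//  * junction: the smallest value a convex left branch can attain at the
//    mode must not exceed the largest value the concave right branch can
//    start from (the jump at the mode must go upward).
// The first two give closed-form per-mode thresholds computed in two
// amortised hull passes; the junction constraint is checked at that
// threshold and, when it binds, the per-mode minimal d is refined by
// bisection. dip = min over modes.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

namespace {

struct Ecdf {
  std::vector<double> u;    // unique sorted values
  std::vector<double> Fat;  // F(u_j)
  std::vector<double> Fb;   // F(u_j^-)
  std::vector<double> pc;   // point mass at u_j
  int k;
};

Ecdf make_ecdf(const Rcpp::NumericVector& xs) {
  Ecdf e;
  const int n = xs.size();
  for (int i = 0; i < n; ++i) {
    if (i == 0 || xs[i] != xs[i - 1]) {
      e.u.push_back(xs[i]);
      e.pc.push_back(0.0);
    }
    e.pc.back() += 1.0 / n;
  }
  e.k = (int)e.u.size();
  e.Fat.resize(e.k);
  e.Fb.resize(e.k);
  double acc = 0.0;
  for (int j = 0; j < e.k; ++j) {
    e.Fb[j] = acc;
    acc += e.pc[j];
    e.Fat[j] = acc;
  }
  return e;
}

// prefix pass: dL[m] = half the max deviation of (u_j, Fat_j), j < m, above
// the lower convex hull of (u_i, Fb_i), i <= m (mode at m has band centred
// on Fb so it contributes no deviation of its own).
void prefix_pass(const Ecdf& e, std::vector<double>& dL) {
  const int k = e.k;
  dL.assign(k, 0.0);
  std::vector<int> hull;
  hull.reserve(k);
  double best = 0.0;
  for (int m = 0; m < k; ++m) {
    if (m >= 1) best = std::max(best, e.pc[m - 1]);
    while (hull.size() >= 2) {
      int i = hull[hull.size() - 2], j = hull.back();
      // pop j if it lies on/above chord i--m (lower hull)
      if ((e.Fb[j] - e.Fb[i]) * (e.u[m] - e.u[i]) -
          (e.Fb[m] - e.Fb[i]) * (e.u[j] - e.u[i]) >= 0.0)
        hull.pop_back();
      else
        break;
    }
    if (!hull.empty()) {
      int i0 = hull.back();
      for (int j = i0 + 1; j < m; ++j) {
        double chord = e.Fb[i0] + (e.Fb[m] - e.Fb[i0]) *
                                      (e.u[j] - e.u[i0]) / (e.u[m] - e.u[i0]);
        best = std::max(best, e.Fat[j] - chord);
      }
    }
    hull.push_back(m);
    dL[m] = best / 2.0;
  }
}

// suffix pass: mirror image for the concave side.
void suffix_pass(const Ecdf& e, std::vector<double>& dR) {
  const int k = e.k;
  dR.assign(k, 0.0);
  std::vector<int> hull;
  hull.reserve(k);
  double best = 0.0;
  for (int m = k - 1; m >= 0; --m) {
    if (m <= k - 2) best = std::max(best, e.pc[m + 1]);
    while (hull.size() >= 2) {
      int i = hull[hull.size() - 2], j = hull.back();
      // pop j if it lies on/below chord i--m (upper hull, walking left)
      if ((e.Fat[j] - e.Fat[i]) * (e.u[m] - e.u[i]) -
          (e.Fat[m] - e.Fat[i]) * (e.u[j] - e.u[i]) >= 0.0)
        hull.pop_back();
      else
        break;
    }
    if (!hull.empty()) {
      int i0 = hull.back();
      for (int j = m + 1; j < i0; ++j) {
        double chord = e.Fat[m] + (e.Fat[i0] - e.Fat[m]) *
                                      (e.u[j] - e.u[m]) / (e.u[i0] - e.u[m]);
        best = std::max(best, chord - e.Fb[j]);
      }
    }
    hull.push_back(m);
    dR[m] = best / 2.0;
  }
}

// minimal value a convex nondecreasing branch within the bands can attain at
// the mode (index m, 0-based); also reports d(a_min)/dd of the active piece
double a_min(const Ecdf& e, int m, double d, double* slope_out) {
  double best = e.Fb[m] - d, slope = -1.0;
  if (best < 0.0) { best = 0.0; slope = 0.0; }
  for (int j = 0; j < m; ++j) {
    double Lj = e.Fat[j] - d, dLj = -1.0;
    if (Lj < 0.0) { Lj = 0.0; dLj = 0.0; }
    if (Lj > best) { best = Lj; slope = dLj; }
    double s = 0.0, ds = 0.0;
    for (int i = 0; i < j; ++i) {
      double Ui = e.Fb[i] + d, dUi = 1.0;
      if (Ui > 1.0) { Ui = 1.0; dUi = 0.0; }
      double inv = 1.0 / (e.u[j] - e.u[i]);
      double cand = (Lj - Ui) * inv;
      if (cand > s) { s = cand; ds = (dLj - dUi) * inv; }
    }
    double w = e.u[m] - e.u[j];
    double val = Lj + s * w;
    if (val > best) { best = val; slope = dLj + ds * w; }
  }
  if (slope_out) *slope_out = slope;
  return best;
}

// maximal value the concave right branch can start from at the mode
double b_max(const Ecdf& e, int m, double d, double* slope_out) {
  const int k = e.k;
  double best = e.Fat[m] + d, slope = 1.0;
  if (best > 1.0) { best = 1.0; slope = 0.0; }
  for (int i = m + 1; i < k; ++i) {
    double Ui = e.Fb[i] + d, dUi = 1.0;
    if (Ui > 1.0) { Ui = 1.0; dUi = 0.0; }
    if (Ui < best) { best = Ui; slope = dUi; }
    double s = 0.0, ds = 0.0;
    for (int j = i + 1; j < k; ++j) {
      double Lj = e.Fat[j] - d, dLj = -1.0;
      if (Lj < 0.0) { Lj = 0.0; dLj = 0.0; }
      double inv = 1.0 / (e.u[j] - e.u[i]);
      double cand = (Lj - Ui) * inv;
      if (cand > s) { s = cand; ds = (dLj - dUi) * inv; }
    }
    double w = e.u[i] - e.u[m];
    double val = Ui - s * w;
    if (val < best) { best = val; slope = dUi - ds * w; }
  }
  if (slope_out) *slope_out = slope;
  return best;
}

// junction gap g(d) = a_min - b_max: convex, piecewise linear, decreasing
// (slope <= -2); feasible iff g(d) <= 0
inline double junction_gap(const Ecdf& e, int m, double d, double* slope_out) {
  double sa, sb;
  double g = a_min(e, m, d, &sa) - b_max(e, m, d, &sb);
  if (slope_out) *slope_out = sa - sb;
  return g;
}

inline bool junction_ok(const Ecdf& e, int m, double d) {
  return junction_gap(e, m, d, nullptr) <= 1e-14;
}

// smallest d >= lo with g(d) <= 0, by Newton on the active linear pieces
// (monotone from the left since g is convex); `hi` is a known-feasible cap
double junction_root(const Ecdf& e, int m, double lo, double hi) {
  double d = lo;
  for (int it = 0; it < 60; ++it) {
    double slope;
    double g = junction_gap(e, m, d, &slope);
    if (g <= 1e-14) return d;
    if (slope >= -1e-12) break;  // defensive; cannot happen for valid bands
    double step = -g / slope;
    if (step < 1e-15) step = 1e-15;
    d += step;
    if (d >= hi) return hi;
  }
  // fallback bisection
  double a = lo, b = hi;
  for (int it = 0; it < 60 && b - a > 1e-14; ++it) {
    double mid = 0.5 * (a + b);
    if (junction_ok(e, m, mid)) b = mid; else a = mid;
  }
  return b;
}

double dip_core(const Rcpp::NumericVector& xs) {
  Ecdf e = make_ecdf(xs);
  if (e.k == 1) return 0.0;
  std::vector<double> dL, dR;
  prefix_pass(e, dL);
  suffix_pass(e, dR);
  std::vector<int> order(e.k);
  for (int m = 0; m < e.k; ++m) order[m] = m;
  std::vector<double> base(e.k);
  for (int m = 0; m < e.k; ++m) base[m] = std::max(dL[m], dR[m]);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return base[a] < base[b]; });
  double best = 0.5;  // dip can never exceed 1/4; safe upper bracket
  for (int idx = 0; idx < e.k; ++idx) {
    int m = order[idx];
    if (base[m] >= best) break;  // no later mode can improve
    if (junction_ok(e, m, base[m])) {
      best = base[m];
      continue;
    }
    if (!junction_ok(e, m, best)) continue;  // cannot beat current best
    best = junction_root(e, m, base[m], best);
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(Rcpp::NumericVector x) {
  Rcpp::NumericVector xs = Rcpp::clone(x).sort();
  return dip_core(xs);
}

// dips of n_boot reference-null samples of size n (uniform(0,1) or standard
// Gaussian), using R's RNG so that set.seed() in R controls the draws
// [[Rcpp::export(name = ".dip_null_cpp")]]
Rcpp::NumericVector dip_null_cpp(int n, int n_boot, bool gaussian) {
  Rcpp::NumericVector out(n_boot);
  Rcpp::NumericVector samp(n);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i)
      samp[i] = gaussian ? R::norm_rand() : R::unif_rand();
    Rcpp::NumericVector xs = Rcpp::clone(samp).sort();
    out[b] = dip_core(xs);
  }
  return out;
}
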