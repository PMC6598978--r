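// Wiener first-passage-time (WFPT) machinery for the diffusion decision model
// with unbiased start (z = a/2) and unit noise. Density evaluation follows the
// standard small-time / large-time series with automatic regime switching
// (truncation tolerance 1e-7 per term sum).

#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

static const double WFPT_EPS = 1e-7;

// Density of first passage at the LOWER boundary at decision time t (t > 0
// already net of non-decision time), for drift v, separation a, relative start w.
// Scaled form: pass u = t / a^2.
static double wfpt_density_lower_raw(double t, double v, double a, double w) {
  if (t <= 0.0 || !R_finite(t)) return 0.0;
  double u = t / (a * a);  // normalized time

  // Navarro & Fuss (regime choice): number of terms needed by each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * WFPT_EPS < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * WFPT_EPS * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * WFPT_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * WFPT_EPS) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double f;  // density in normalized time for v = 0, a = 1
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    double s = 0.0;
    for (int k = -((K - 1) / 2); k <= ((K - 1) / 2) + ((K - 1) % 2); ++k) {
      double wk = w + 2.0 * k;
      s += wk * std::exp(-wk * wk / (2.0 * u));
    }
    f = s / std::sqrt(2.0 * M_PI * u * u * u);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f = s * M_PI;
  }
  if (f < 0.0) f = 0.0;  // truncation can leave tiny negative values

  // un-normalize: drift and boundary scaling
  return f * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
}

// Defective density of passage at boundary (+1 upper / -1 lower) at clock time
// rt, given drift v, separation a, non-decision time ndt. Upper-boundary
// passage equals lower-boundary passage under (v -> -v, w -> 1 - w).
double wfpt_density_scalar(double rt, int boundary, double v, double a,
                           double ndt, double w) {
  double t = rt - ndt;
  if (t <= 0.0) return 0.0;
  if (boundary > 0) return wfpt_density_lower_raw(t, -v, a, 1.0 - w);
  return wfpt_density_lower_raw(t, v, a, w);
}

// [[Rcpp::export]]
NumericVector cpp_wfpt_density(NumericVector rt, IntegerVector boundary,
                               NumericVector v, NumericVector a,
                               NumericVector ndt, double w) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ai = a[a.size() == 1 ? 0 : i];
    if (ai <= 0.0) stop("threshold separation 'a' must be > 0");
    out[i] = wfpt_density_scalar(rt[i], boundary[boundary.size() == 1 ? 0 : i],
                              v[v.size() == 1 ? 0 : i], ai,
                              ndt[ndt.size() == 1 ? 0 : i], w);
  }
  return out;
}

// Sum of log densities; -Inf if any trial has rt <= ndt (sampler-rejectable).
// [[Rcpp::export]]
double cpp_wfpt_loglik(NumericVector rt, IntegerVector boundary,
                       NumericVector v, NumericVector a, NumericVector ndt,
                       double w) {
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double ai = a[a.size() == 1 ? 0 : i];
    if (ai <= 0.0) stop("threshold separation 'a' must be > 0");
    double d = wfpt_density_scalar(rt[i], boundary[boundary.size() == 1 ? 0 : i],
                                v[v.size() == 1 ? 0 : i], ai,
                                ndt[ndt.size() == 1 ? 0 : i], w);
    if (d <= 0.0 || !R_finite(d)) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// Euler-Maruyama simulation of the bounded accumulator. Uses R's RNG so that
// set.seed() governs reproducibility. Returns a 2-column matrix (boundary, rt).
// max_t caps the decision time (flagged as boundary 0, rt NA) to avoid
// unbounded loops at pathological drifts.
// [[Rcpp::export]]
NumericMatrix cpp_sim_ddm(int n, NumericVector v, NumericVector a,
                          NumericVector ndt, double w, double dt,
                          double max_t) {
  NumericMatrix out(n, 2);
  double sq_dt = std::sqrt(dt);
  int max_steps = (int)std::ceil(max_t / dt);
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double ai = a[a.size() == 1 ? 0 : i];
    double ndti = ndt[ndt.size() == 1 ? 0 : i];
    if (ai <= 0.0) stop("threshold separation 'a' must be > 0");
    double x = w * ai;
    int steps = 0;
    int bnd = 0;
    while (steps < max_steps) {
      x += vi * dt + sq_dt * norm_rand();
      ++steps;
      if (x >= ai) { bnd = 1; break; }
      if (x <= 0.0) { bnd = -1; break; }
    }
    if (bnd == 0) {
      out(i, 0) = 0;
      out(i, 1) = NA_REAL;
    } else {
      out(i, 0) = bnd;
      out(i, 1) = steps * dt + ndti;
    }
  }
  return out;
}
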