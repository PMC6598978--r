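// Per-participant slice-sampling scans, specialized per model so the whole
// coordinate sweep runs without leaving compiled code. Each scan does one
// stepping-out slice update per coordinate (slice width in units of the
// group SD) plus a few random-direction slice updates that pick up
// posterior correlation between coordinates (e.g. the context-value
// learning rate and the NDT slope, which share the non-decision-time
// pathway). Uses R's RNG throughout.

#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

double cpp_rlddm_loglik(IntegerVector session, IntegerVector context,
                        IntegerVector correct, NumericVector rt,
                        NumericVector R_ch, NumericVector R_un,
                        IntegerVector complete, NumericVector params,
                        bool reset_per_session);
double cpp_wfpt_loglik(NumericVector rt, IntegerVector boundary,
                       NumericVector v, NumericVector a, NumericVector ndt,
                       double w);

typedef std::function<double(const std::vector<double>&)> LoglikFn;

static double dnorm_log(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.918938533204672742 - std::log(s) - 0.5 * z * z;
}

// one stepping-out slice update along direction d from theta (in place);
// lp(theta) = loglik + sum_k dnorm(theta_k; mu_k, sigma_k). ll_cur is the
// cached loglik at the current theta and is updated on move.
static void slice_line(std::vector<double>& theta, double& ll_cur,
                       const std::vector<double>& d,
                       const std::vector<double>& mu,
                       const std::vector<double>& sigma,
                       const LoglikFn& loglik, double w, int max_step) {
  int K = theta.size();
  std::vector<double> cand(K);
  double prior0 = 0.0;
  for (int k = 0; k < K; ++k) prior0 += dnorm_log(theta[k], mu[k], sigma[k]);
  double lp0 = ll_cur + prior0;
  double ll_cand = 0.0;
  auto lp_at = [&](double t) {
    for (int k = 0; k < K; ++k) cand[k] = theta[k] + t * d[k];
    double l = loglik(cand);
    if (!R_finite(l)) { ll_cand = R_NegInf; return R_NegInf; }
    ll_cand = l;
    double pr = 0.0;
    for (int k = 0; k < K; ++k) pr += dnorm_log(cand[k], mu[k], sigma[k]);
    return l + pr;
  };
  double ly = lp0 - exp_rand();
  double L = -unif_rand() * w;
  double Rr = L + w;
  for (int s = 0; s < max_step && lp_at(L) > ly; ++s) L -= w;
  for (int s = 0; s < max_step && lp_at(Rr) > ly; ++s) Rr += w;
  for (;;) {
    double t1 = L + unif_rand() * (Rr - L);
    double lp1 = lp_at(t1);
    if (lp1 >= ly) {
      for (int k = 0; k < K; ++k) theta[k] += t1 * d[k];
      ll_cur = ll_cand;
      return;
    }
    if (t1 < 0) L = t1; else Rr = t1;
    if (Rr - L < 1e-12) return;  // numerically stuck: keep current point
  }
}

static NumericVector slice_scan_impl(NumericVector theta0, double ll0,
                                     NumericVector gmu, NumericVector sigma,
                                     double w, int n_dir,
                                     const LoglikFn& loglik,
                                     const std::vector<std::pair<int, int> >&
                                         pairs = {}) {
  int K = theta0.size();
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> mu(gmu.begin(), gmu.end());
  std::vector<double> sg(sigma.begin(), sigma.end());
  double ll = ll0;
  std::vector<double> d(K, 0.0);
  // coordinate scan
  for (int k = 0; k < K; ++k) {
    std::fill(d.begin(), d.end(), 0.0);
    d[k] = 1.0;
    slice_line(theta, ll, d, mu, sg, loglik, w * sg[k], 8);
  }
  // random-direction updates, direction scaled by the group SDs so the
  // line respects the funnel geometry
  for (int r = 0; r < n_dir; ++r) {
    double nrm = 0.0;
    for (int k = 0; k < K; ++k) { d[k] = norm_rand(); nrm += d[k] * d[k]; }
    nrm = std::sqrt(nrm);
    for (int k = 0; k < K; ++k) d[k] = d[k] / nrm * sg[k];
    slice_line(theta, ll, d, mu, sg, loglik, w, 8);
  }
  // structural pair diagonals: coordinates that trade off through a shared
  // pathway form posterior ridges that axis and random directions traverse
  // slowly; both diagonals of each flagged pair get a line update
  const double isq2 = 0.70710678118654752;
  for (size_t p = 0; p < pairs.size(); ++p) {
    int k1 = pairs[p].first, k2 = pairs[p].second;
    for (int sgn = -1; sgn <= 1; sgn += 2) {
      std::fill(d.begin(), d.end(), 0.0);
      d[k1] = isq2 * sg[k1];
      d[k2] = sgn * isq2 * sg[k2];
      slice_line(theta, ll, d, mu, sg, loglik, w, 8);
    }
  }
  NumericVector out(K + 1);
  for (int k = 0; k < K; ++k) out[k] = theta[k];
  out[K] = ll;
  return out;
}

// learning-diffusion model: theta is the 8-vector on the unconstrained scale
// [[Rcpp::export]]
NumericVector cpp_rlddm_slice_scan(IntegerVector session,
                                   IntegerVector context,
                                   IntegerVector correct, NumericVector rt,
                                   NumericVector R_ch, NumericVector R_un,
                                   IntegerVector complete,
                                   bool reset_per_session,
                                   NumericVector theta0, double ll0,
                                   NumericVector gmu, NumericVector sigma,
                                   double w, int n_dir) {
  NumericVector nat(8);
  LoglikFn loglik = [&](const std::vector<double>& th) {
    nat[0] = 1.0 / (1.0 + std::exp(-th[0]));
    nat[1] = 1.0 / (1.0 + std::exp(-th[1]));
    nat[2] = 1.0 / (1.0 + std::exp(-th[2]));
    nat[3] = th[3];
    nat[4] = std::exp(th[4]);
    nat[5] = 1.0 / (1.0 + std::exp(-th[5]));
    nat[6] = th[6];
    nat[7] = th[7];
    return cpp_rlddm_loglik(session, context, correct, rt, R_ch, R_un,
                            complete, nat, reset_per_session);
  };
  // (a_int, a_coeff): threshold level vs conflict discount;
  // (ndt_int, ndt_coeff) and (alpha_v, ndt_coeff): the NDT pathway
  std::vector<std::pair<int, int> > pairs = {{4, 5}, {6, 7}, {2, 7}};
  return slice_scan_impl(theta0, ll0, gmu, sigma, w, n_dir, loglik, pairs);
}

// batch evaluation of all participants' log-likelihoods at a matrix of
// unconstrained parameter rows (used by the non-centered group moves)
// [[Rcpp::export]]
NumericVector cpp_rlddm_loglik_batch(List pds, NumericMatrix theta,
                                     bool reset_per_session) {
  int J = pds.size();
  NumericVector out(J);
  NumericVector nat(8);
  for (int j = 0; j < J; ++j) {
    List pd = pds[j];
    nat[0] = 1.0 / (1.0 + std::exp(-theta(j, 0)));
    nat[1] = 1.0 / (1.0 + std::exp(-theta(j, 1)));
    nat[2] = 1.0 / (1.0 + std::exp(-theta(j, 2)));
    nat[3] = theta(j, 3);
    nat[4] = std::exp(theta(j, 4));
    nat[5] = 1.0 / (1.0 + std::exp(-theta(j, 5)));
    nat[6] = theta(j, 6);
    nat[7] = theta(j, 7);
    out[j] = cpp_rlddm_loglik(pd["session"], pd["context"], pd["correct"],
                              pd["rt"], pd["R_ch"], pd["R_un"],
                              pd["complete"], nat, reset_per_session);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_factorial_loglik_batch(List fds, NumericMatrix theta) {
  int J = fds.size();
  NumericVector out(J);
  for (int j = 0; j < J; ++j) {
    List fd = fds[j];
    NumericVector rt = fd["rt"];
    IntegerVector boundary = fd["boundary"];
    NumericMatrix X = fd["X"];
    int n = rt.size();
    NumericVector v(n), a(n), ndt(n);
    for (int i = 0; i < n; ++i) {
      double ev = 0.0, ea = 0.0, en = 0.0;
      for (int c = 0; c < 4; ++c) {
        double x = X(i, c);
        ev += x * theta(j, c);
        ea += x * theta(j, 4 + c);
        en += x * theta(j, 8 + c);
      }
      v[i] = ev;
      a[i] = std::exp(ea);
      ndt[i] = std::exp(en);
    }
    out[j] = cpp_wfpt_loglik(rt, boundary, v, a, ndt, 0.5);
  }
  return out;
}

// factorial model: theta is the 12-vector (v block, a block, ndt block),
// X the n x 4 design matrix, boundary +1/-1
// [[Rcpp::export]]
NumericVector cpp_factorial_slice_scan(NumericVector rt,
                                       IntegerVector boundary,
                                       NumericMatrix X,
                                       NumericVector theta0, double ll0,
                                       NumericVector gmu,
                                       NumericVector sigma, double w,
                                       int n_dir) {
  int n = rt.size();
  NumericVector v(n), a(n), ndt(n);
  LoglikFn loglik = [&](const std::vector<double>& th) {
    for (int i = 0; i < n; ++i) {
      double ev = 0.0, ea = 0.0, en = 0.0;
      for (int c = 0; c < 4; ++c) {
        double x = X(i, c);
        ev += x * th[c];
        ea += x * th[4 + c];
        en += x * th[8 + c];
      }
      v[i] = ev;
      a[i] = std::exp(ea);
      ndt[i] = std::exp(en);
    }
    return cpp_wfpt_loglik(rt, boundary, v, a, ndt, 0.5);
  };
  return slice_scan_impl(theta0, ll0, gmu, sigma, w, n_dir, loglik);
}
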