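// Context-dependent Q-learning (chosen/unchosen/context-value delta rules)
// with trial-wise linking to DDM parameters, plus a combined per-participant
// log-likelihood and a full agent simulator used by the cohort generator.

#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

// defined in wfpt.cpp
double cpp_wfpt_loglik(NumericVector rt, IntegerVector boundary,
                       NumericVector v, NumericVector a, NumericVector ndt,
                       double w);
NumericMatrix cpp_sim_ddm(int n, NumericVector v, NumericVector a,
                          NumericVector ndt, double w, double dt, double max_t);

struct RelState { double qcor, qinc, V; };

struct RelParams {
  double alpha_c, alpha_u, alpha_v, v_coeff, a_int, a_coeff, ndt_int, ndt_coeff;
};

static RelParams unpack_params(NumericVector p) {
  if (p.size() != 8) stop("params must have length 8");
  RelParams out = {p[0], p[1], p[2], p[3], p[4], p[5], p[6], p[7]};
  if (out.alpha_c < 0 || out.alpha_c > 1 || out.alpha_u < 0 || out.alpha_u > 1 ||
      out.alpha_v < 0 || out.alpha_v > 1)
    stop("learning rates must lie in [0, 1]");
  if (out.a_int <= 0) stop("a_int must be > 0");
  if (out.a_coeff < 0 || out.a_coeff > 1) stop("a_coeff must lie in [0, 1]");
  return out;
}

static void link_state(const RelState& s, const RelParams& p, double* v_t,
                       double* a_t, double* ndt_t, double* dQ, double* conf) {
  *dQ = s.qcor - s.qinc;
  *conf = 1.0 / (std::fabs(*dQ) + 1.0);
  *v_t = p.v_coeff * (*dQ);
  *a_t = p.a_int * (1.0 + p.a_coeff * (*conf - 1.0));
  *ndt_t = std::exp(p.ndt_int + p.ndt_coeff * s.V);
}

// One learning update. chose_correct selects which Q plays "chosen".
// Prediction errors use the pre-trial V as reference; under partial feedback
// the unchosen Q is inert and the context prediction error substitutes the
// unchosen option's Q for its unseen outcome.
static void update_state(RelState& s, const RelParams& p, bool chose_correct,
                         double R_ch, double R_un, bool complete, double* d_c,
                         double* d_u, double* d_V) {
  double V0 = s.V;
  double* Qch = chose_correct ? &s.qcor : &s.qinc;
  double* Qun = chose_correct ? &s.qinc : &s.qcor;
  *d_c = R_ch - V0 - *Qch;
  *Qch += p.alpha_c * (*d_c);
  if (complete) {
    *d_u = R_un - V0 - *Qun;
    *Qun += p.alpha_u * (*d_u);
    *d_V = (R_ch + R_un) / 2.0 - V0;
  } else {
    *d_u = NA_REAL;
    *d_V = (R_ch + *Qun) / 2.0 - V0;
  }
  s.V = V0 + p.alpha_v * (*d_V);
}

// session/context bookkeeping: states indexed by context (0..3), reset when
// the session label changes (reset_per_session) or carried over otherwise.
class StateTracker {
 public:
  StateTracker(bool reset) : reset_(reset), cur_session_(NA_INTEGER) {
    for (int c = 0; c < 4; ++c) st_[c] = {0.0, 0.0, 0.0};
  }
  RelState& at(int session, int context) {
    if (context < 0 || context > 3) stop("context index out of range");
    if (cur_session_ == NA_INTEGER) cur_session_ = session;
    if (session != cur_session_) {
      if (reset_)
        for (int c = 0; c < 4; ++c) st_[c] = {0.0, 0.0, 0.0};
      cur_session_ = session;
    }
    return st_[context];
  }
 private:
  bool reset_;
  int cur_session_;
  RelState st_[4];
};

// Trace columns, one row per trial (pre-update values for that trial).
// [[Rcpp::export]]
NumericMatrix cpp_forward_pass(IntegerVector session, IntegerVector context,
                               IntegerVector correct, NumericVector R_ch,
                               NumericVector R_un, IntegerVector complete,
                               NumericVector params, bool reset_per_session) {
  RelParams p = unpack_params(params);
  int n = session.size();
  NumericMatrix out(n, 11);
  colnames(out) = CharacterVector::create(
      "Q_cor", "Q_inc", "V", "delta_Q", "conflict", "v_t", "a_t", "ndt_t",
      "delta_c", "delta_u", "delta_V");
  StateTracker trk(reset_per_session);
  for (int i = 0; i < n; ++i) {
    RelState& s = trk.at(session[i], context[i]);
    double v_t, a_t, ndt_t, dQ, conf;
    link_state(s, p, &v_t, &a_t, &ndt_t, &dQ, &conf);
    out(i, 0) = s.qcor; out(i, 1) = s.qinc; out(i, 2) = s.V;
    out(i, 3) = dQ; out(i, 4) = conf;
    out(i, 5) = v_t; out(i, 6) = a_t; out(i, 7) = ndt_t;
    if (correct[i] == NA_INTEGER) {  // non-response: no feedback processed
      out(i, 8) = NA_REAL; out(i, 9) = NA_REAL; out(i, 10) = NA_REAL;
      continue;
    }
    double d_c, d_u, d_V;
    update_state(s, p, correct[i] == 1, R_ch[i], R_un[i], complete[i] == 1,
                 &d_c, &d_u, &d_V);
    out(i, 8) = d_c; out(i, 9) = d_u; out(i, 10) = d_V;
  }
  return out;
}

// Per-participant joint choice/RT log-likelihood: forward pass feeding the
// WFPT density at each responded trial (correct -> upper boundary).
// [[Rcpp::export]]
double cpp_rlddm_loglik(IntegerVector session, IntegerVector context,
                        IntegerVector correct, NumericVector rt,
                        NumericVector R_ch, NumericVector R_un,
                        IntegerVector complete, NumericVector params,
                        bool reset_per_session) {
  RelParams p = unpack_params(params);
  int n = session.size();
  StateTracker trk(reset_per_session);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    RelState& s = trk.at(session[i], context[i]);
    double v_t, a_t, ndt_t, dQ, conf;
    link_state(s, p, &v_t, &a_t, &ndt_t, &dQ, &conf);
    if (correct[i] == NA_INTEGER) continue;  // excluded from the likelihood
    double di = wfpt_density_scalar(rt[i], correct[i] == 1 ? 1 : -1, v_t,
                                    a_t, ndt_t, 0.5);
    if (di <= 0.0 || !R_finite(di)) return R_NegInf;
    ll += std::log(di);
    double d_c, d_u, d_V;
    update_state(s, p, correct[i] == 1, R_ch[i], R_un[i], complete[i] == 1,
                 &d_c, &d_u, &d_V);
  }
  return ll;
}

// Same likelihood, taking the sampler's unconstrained parameter vector
// (logit learning rates and threshold coefficient, log threshold intercept)
// so the hot loop avoids R-side transforms.
// [[Rcpp::export]]
double cpp_rlddm_loglik_unc(IntegerVector session, IntegerVector context,
                            IntegerVector correct, NumericVector rt,
                            NumericVector R_ch, NumericVector R_un,
                            IntegerVector complete, NumericVector theta,
                            bool reset_per_session) {
  if (theta.size() != 8) stop("theta must have length 8");
  NumericVector nat(8);
  nat[0] = 1.0 / (1.0 + std::exp(-theta[0]));
  nat[1] = 1.0 / (1.0 + std::exp(-theta[1]));
  nat[2] = 1.0 / (1.0 + std::exp(-theta[2]));
  nat[3] = theta[3];
  nat[4] = std::exp(theta[4]);
  nat[5] = 1.0 / (1.0 + std::exp(-theta[5]));
  nat[6] = theta[6];
  nat[7] = theta[7];
  return cpp_rlddm_loglik(session, context, correct, rt, R_ch, R_un,
                          complete, nat, reset_per_session);
}

// Simulate one agent over a fixed outcome schedule. outcome_cor/outcome_inc
// are the potential payoffs of the correct (best) and incorrect (worst) cue.
// Returns per-trial behavior plus the latent ground truth used to produce it.
// [[Rcpp::export]]
NumericMatrix cpp_sim_agent(IntegerVector session, IntegerVector context,
                            IntegerVector complete, NumericVector outcome_cor,
                            NumericVector outcome_inc, NumericVector params,
                            double response_window, double dt,
                            bool reset_per_session) {
  RelParams p = unpack_params(params);
  int n = session.size();
  NumericMatrix out(n, 11);
  colnames(out) = CharacterVector::create(
      "correct", "rt", "outcome_chosen", "outcome_unchosen", "Q_cor", "Q_inc",
      "V", "delta_Q", "v_t", "a_t", "ndt_t");
  StateTracker trk(reset_per_session);
  NumericVector v1(1), a1(1), ndt1(1);
  for (int i = 0; i < n; ++i) {
    RelState& s = trk.at(session[i], context[i]);
    double v_t, a_t, ndt_t, dQ, conf;
    link_state(s, p, &v_t, &a_t, &ndt_t, &dQ, &conf);
    out(i, 4) = s.qcor; out(i, 5) = s.qinc; out(i, 6) = s.V; out(i, 7) = dQ;
    out(i, 8) = v_t; out(i, 9) = a_t; out(i, 10) = ndt_t;
    v1[0] = v_t; a1[0] = a_t; ndt1[0] = ndt_t;
    NumericMatrix one = cpp_sim_ddm(1, v1, a1, ndt1, 0.5, dt,
                                    response_window + 5.0);
    bool responded = one(0, 0) != 0 && R_finite(one(0, 1)) &&
                     one(0, 1) <= response_window;
    if (!responded) {  // late or capped: non-response, no learning
      out(i, 0) = NA_REAL; out(i, 1) = NA_REAL;
      out(i, 2) = NA_REAL; out(i, 3) = NA_REAL;
      continue;
    }
    bool chose_correct = one(0, 0) > 0;
    double R_ch = chose_correct ? outcome_cor[i] : outcome_inc[i];
    double R_un = chose_correct ? outcome_inc[i] : outcome_cor[i];
    out(i, 0) = chose_correct ? 1.0 : 0.0;
    out(i, 1) = one(0, 1);
    out(i, 2) = R_ch;
    out(i, 3) = complete[i] == 1 ? R_un : NA_REAL;
    double d_c, d_u, d_V;
    update_state(s, p, chose_correct, R_ch,
                 complete[i] == 1 ? R_un : NA_REAL, complete[i] == 1, &d_c,
                 &d_u, &d_V);
  }
  return out;
}
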