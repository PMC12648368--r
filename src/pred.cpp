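// Analytic concentration predictions for the transit-absorption,
// two-compartment disposition model with a first-order effect compartment
// (PBMC link), plus the per-subject joint -2 log-likelihood used by the
// Laplace marginal-likelihood estimator.
//
// Key identity: the drug input to the absorption compartment after a chain
// of NN+1 transit steps at rate ktr = (NN+1)/MTT is a gamma density with
// shape alpha = NN+1 and rate ktr (supports non-integer NN).  The bolus
// response of the remaining linear system is a sum of exponentials, so the
// full response is a per-pole convolution of an exponential with the gamma
// input:
//   E(lambda, u) = int_0^u g(s) exp(-lambda (u - s)) ds
//                = exp(-lambda u) (ktr/(ktr-lambda))^alpha P(alpha, (ktr-lambda) u)
// where P is the regularised lower incomplete gamma function; a numeric
// quadrature fallback covers ktr <= lambda.

#include <Rcpp.h>
using namespace Rcpp;

// 20-node Gauss-Legendre abscissae/weights on [-1, 1]
static const double GLX[20] = {
  -0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
  -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
  -0.5108670019508271, -0.3737060887154195, -0.2277858511416451,
  -0.0765265211334973,  0.0765265211334973,  0.2277858511416451,
   0.3737060887154195,  0.5108670019508271,  0.6360536807265150,
   0.7463319064601508,  0.8391169718222188,  0.9122344282513259,
   0.9639719272779138,  0.9931285991850949 };
static const double GLW[20] = {
  0.0176140071391521, 0.0406014298003869, 0.0626720483341091,
  0.0832767415767048, 0.1019301198172404, 0.1181945319615184,
  0.1316886384491766, 0.1420961093183820, 0.1491729864726037,
  0.1527533871307258, 0.1527533871307258, 0.1491729864726037,
  0.1420961093183820, 0.1316886384491766, 0.1181945319615184,
  0.1019301198172404, 0.0832767415767048, 0.0626720483341091,
  0.0406014298003869, 0.0176140071391521 };

// Convolution of the gamma(alpha, ktr) input density with exp(-lambda t).
static double egam(double lam, double u, double ktr, double alpha) {
  if (u <= 0.0) return 0.0;
  double mu = ktr - lam;
  if (mu > 1e-6 * ktr) {
    double x = mu * u;
    double lg = 0.0;
    if (x < alpha + 8.0 * std::sqrt(alpha) + 25.0)
      lg = R::pgamma(x, alpha, 1.0, 1, 1);
    double lt = alpha * (std::log(ktr) - std::log(mu)) - lam * u + lg;
    return (lt < -700.0) ? 0.0 : std::exp(lt);
  }
  // lambda close to or above ktr: numeric convolution over the gamma support
  double shi = R::qgamma(0.99999, alpha, 1.0 / ktr, 1, 0);
  if (shi > u) shi = u;
  double acc = 0.0, h = 0.5 * shi;
  for (int k = 0; k < 20; ++k) {
    double s = h * (GLX[k] + 1.0);
    double g = R::dgamma(s, alpha, 1.0 / ktr, 0);
    acc += GLW[k] * g * std::exp(-lam * (u - s));
  }
  return acc * h;
}

struct PolySys {
  int np;          // number of plasma poles (2 or 3)
  double lam[4];   // poles; index np holds ke0 (effect compartment)
  double ap[4];    // plasma conc coefficients per unit absorbed amount
  double ae[4];    // effect-compartment coefficients (np + 1 poles)
};

static void nudge_distinct(double *L, int n) {
  for (int pass = 0; pass < 3; ++pass)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double m = std::max(std::abs(L[i]), std::abs(L[j]));
        if (std::abs(L[i] - L[j]) < 1e-8 * m + 1e-12) L[j] *= 1.000001;
      }
}

// Partial-fraction system for a bolus into the absorption compartment.
static void build_sys(double cl, double v, double q, double vp,
                      double ka, double ke0, PolySys &S) {
  double k10 = cl / v;
  if (q > 0.0 && vp > 0.0) {
    double k12 = q / v, k21 = q / vp;
    double b = k10 + k12 + k21, c = k10 * k21;
    double disc = b * b - 4.0 * c;
    disc = disc > 0.0 ? std::sqrt(disc) : 0.0;
    double L[3] = { 0.5 * (b + disc), 0.5 * (b - disc), ka };
    nudge_distinct(L, 3);
    for (int i = 0; i < 3; ++i) {
      double den = 1.0;
      for (int j = 0; j < 3; ++j) if (j != i) den *= (L[j] - L[i]);
      S.lam[i] = L[i];
      S.ap[i] = ka * (k21 - L[i]) / den / v;
    }
    S.np = 3;
  } else {
    double L[2] = { k10, ka };
    nudge_distinct(L, 2);
    S.lam[0] = L[0]; S.lam[1] = L[1];
    S.ap[0] = ka / (L[1] - L[0]) / v;
    S.ap[1] = ka / (L[0] - L[1]) / v;
    S.np = 2;
  }
  double ke = ke0;
  for (int i = 0; i < S.np; ++i)
    if (std::abs(ke - S.lam[i]) < 1e-8 * std::max(ke, S.lam[i]) + 1e-12)
      ke *= 1.000001;
  double tot = 0.0;
  for (int i = 0; i < S.np; ++i) {
    double bi = S.ap[i] * ke / (ke - S.lam[i]);
    S.ae[i] = bi; tot += bi;
  }
  S.lam[S.np] = ke;
  S.ae[S.np] = -tot;
}

// Single-dose contribution at u = t - t_dose (both matrices).
static void dose_conc(const PolySys &S, double fd, double ktr, double alpha,
                      double u, double &cp, double &ce) {
  cp = 0.0; ce = 0.0;
  if (u <= 0.0) return;
  for (int i = 0; i < S.np; ++i) cp += S.ap[i] * egam(S.lam[i], u, ktr, alpha);
  for (int i = 0; i <= S.np; ++i) ce += S.ae[i] * egam(S.lam[i], u, ktr, alpha);
  cp *= fd; ce *= fd;
}

// Steady-state train of identical typical doses, last one at u0 >= tau back.
// Transit input is complete (>= one dosing interval old): the incomplete
// gamma factor is 1, but the gamma delay's moment factor
// (ktr/(ktr-lambda))^alpha remains, and each pole sums geometrically.
// Poles with lambda >= ktr decay at least as fast as the gamma tail and are
// negligible one interval after dosing.
static double train_pole(double lam, double tau, double u0,
                         double ktr, double alpha) {
  double mu = ktr - lam;
  if (mu <= 1e-6 * ktr || lam * u0 > 600.0) return 0.0;
  double lt = alpha * (std::log(ktr) - std::log(mu)) - lam * u0;
  if (lt < -700.0) return 0.0;
  return std::exp(lt) / (1.0 - std::exp(-lam * tau));
}

static void train_conc(const PolySys &S, double fd, double tau, double u0,
                       double ktr, double alpha, double &cp, double &ce) {
  cp = 0.0; ce = 0.0;
  for (int i = 0; i < S.np; ++i)
    cp += S.ap[i] * train_pole(S.lam[i], tau, u0, ktr, alpha);
  for (int i = 0; i <= S.np; ++i)
    ce += S.ae[i] * train_pole(S.lam[i], tau, u0, ktr, alpha);
  cp *= fd; ce *= fd;
}

// Visit-level prediction: steady-state background train (typical absorption)
// up to the unobserved pre-visit dose at -tau, explicit unobserved dose at
// -tau (its own occasion etas), explicit observed dose at 0.
// pars: cl v q vp ka mtt nn f ke0 ppc ; eta6: ka_o mtt_o f_o ka_u mtt_u f_u
static void visit_conc_core(const double *trel, int n, double tau, double amt,
                            const double *pars, const double *eta6,
                            double *plasma, double *pbmc) {
  double cl = pars[0], v = pars[1], q = pars[2], vp = pars[3];
  double ka = pars[4], mtt = pars[5], nn = pars[6], f = pars[7];
  double ke0 = pars[8], ppc = pars[9];
  double alpha = nn + 1.0;

  PolySys St, So, Su;
  build_sys(cl, v, q, vp, ka, ke0, St);
  double ka_o = ka * std::exp(eta6[0]), mtt_o = mtt * std::exp(eta6[1]);
  double f_o = f * std::exp(eta6[2]);
  double ka_u = ka * std::exp(eta6[3]), mtt_u = mtt * std::exp(eta6[4]);
  double f_u = f * std::exp(eta6[5]);
  build_sys(cl, v, q, vp, ka_o, ke0, So);
  build_sys(cl, v, q, vp, ka_u, ke0, Su);
  double ktr_t = alpha / mtt, ktr_o = alpha / mtt_o, ktr_u = alpha / mtt_u;

  for (int k = 0; k < n; ++k) {
    double cp, ce, P = 0.0, E = 0.0;
    train_conc(St, f * amt, tau, trel[k] + 2.0 * tau, ktr_t, alpha, cp, ce);
    P += cp; E += ce;
    dose_conc(Su, f_u * amt, ktr_u, alpha, trel[k] + tau, cp, ce);
    P += cp; E += ce;
    dose_conc(So, f_o * amt, ktr_o, alpha, trel[k], cp, ce);
    P += cp; E += ce;
    plasma[k] = P;
    pbmc[k] = ppc * E;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_visit_conc(NumericVector trel, double tau, double amt,
                             NumericVector pars, NumericVector eta6) {
  int n = trel.size();
  NumericMatrix out(n, 2);
  std::vector<double> pl(n), pb(n);
  visit_conc_core(REAL(trel), n, tau, amt, REAL(pars), REAL(eta6),
                  pl.data(), pb.data());
  for (int i = 0; i < n; ++i) { out(i, 0) = pl[i]; out(i, 1) = pb[i]; }
  colnames(out) = CharacterVector::create("plasma", "pbmc");
  return out;
}

// Explicit superposition over a list of doses sharing disposition parameters
// but with per-dose bioavailability/absorption parameters.
// [[Rcpp::export]]
NumericMatrix cpp_conc_profile(NumericVector times, NumericVector dose_t,
                               NumericVector dose_amt, NumericVector dose_f,
                               NumericVector dose_ka, NumericVector dose_mtt,
                               double cl, double v, double q, double vp,
                               double nn, double ke0, double ppc) {
  int n = times.size(), nd = dose_t.size();
  double alpha = nn + 1.0;
  NumericMatrix out(n, 2);
  for (int d = 0; d < nd; ++d) {
    PolySys S;
    build_sys(cl, v, q, vp, dose_ka[d], ke0, S);
    double ktr = alpha / dose_mtt[d];
    double fd = dose_f[d] * dose_amt[d];
    for (int k = 0; k < n; ++k) {
      double u = times[k] - dose_t[d];
      if (u <= 0.0) continue;
      double cp, ce;
      dose_conc(S, fd, ktr, alpha, u, cp, ce);
      out(k, 0) += cp;
      out(k, 1) += ppc * ce;
    }
  }
  colnames(out) = CharacterVector::create("plasma", "pbmc");
  return out;
}

// ---------------------------------------------------------------------------
// Per-subject joint -2 log density for the Laplace estimator.
//
// eta layout (length 29):
//   [0]          bsv on CL (all visits)
//   [1..4]       bvv on CL, per visit
//   [5+6(v-1)+j] per-visit occasion etas, j = 0..5:
//                ka_obs, mtt_obs, f_obs, ka_unobs, mtt_unobs, f_unobs
// obs columns: visit trel dv mtype blq lloq
// vis columns: tau amt           (one row per visit)
// vispars row per visit: cl v q vp ka mtt nn f ke0 ppc (typical, covariates
//                         and body-size scaling already applied)
// errw: prop_pl add_pl prop_pb add_pb
// om:   w_bsv w_bvv w_ka w_mtt w_f unobs_scale
// active: 0/1 mask over the 29 etas (inactive etas must be 0)

static double omega_for(int idx, const double *om) {
  if (idx == 0) return om[0];
  if (idx <= 4) return om[1];
  int j = (idx - 5) % 6;
  double w = (j % 3 == 0) ? om[2] : (j % 3 == 1) ? om[3] : om[4];
  if (j >= 3) w *= om[5];
  return w;
}

static void visit_pred_core(const double *eta, const NumericMatrix &obs,
                            const NumericMatrix &vis,
                            const NumericMatrix &vispars, int v,
                            double *pred);

static void subject_pred_core(const double *eta, const NumericMatrix &obs,
                              const NumericMatrix &vis,
                              const NumericMatrix &vispars, double *pred) {
  for (int v = 1; v <= vis.nrow(); ++v)
    visit_pred_core(eta, obs, vis, vispars, v, pred);
}

// Predictions for the observations of one visit only (eta layout as above).
static void visit_pred_core(const double *eta, const NumericMatrix &obs,
                            const NumericMatrix &vis,
                            const NumericMatrix &vispars, int v,
                            double *pred /* full-length, rows of v filled */) {
  int nobs = obs.nrow();
  std::vector<double> trel;
  std::vector<int> idx;
  for (int i = 0; i < nobs; ++i)
    if ((int)obs(i, 0) == v) { trel.push_back(obs(i, 1)); idx.push_back(i); }
  if (trel.empty()) return;
  double pars[10];
  for (int j = 0; j < 10; ++j) pars[j] = vispars(v - 1, j);
  pars[0] *= std::exp(eta[0] + eta[v]);
  const double *e6 = eta + 5 + 6 * (v - 1);
  int n = trel.size();
  std::vector<double> pl(n), pb(n);
  visit_conc_core(trel.data(), n, vis(v - 1, 0), vis(v - 1, 1), pars, e6,
                  pl.data(), pb.data());
  for (int k = 0; k < n; ++k)
    pred[idx[k]] = (obs(idx[k], 3) > 0.5) ? pb[k] : pl[k];
}

static double resid_ll_rows(const double *pred, const NumericMatrix &obs,
                            const double *errw, int v /* -1 = all */) {
  int nobs = obs.nrow();
  double ll = 0.0;
  for (int i = 0; i < nobs; ++i) {
    if (v > 0 && (int)obs(i, 0) != v) continue;
    double p = pred[i] > 0.0 ? pred[i] : 0.0;
    bool pb = obs(i, 3) > 0.5;
    double prop = pb ? errw[2] : errw[0];
    double add = pb ? errw[3] : errw[1];
    if (obs(i, 4) > 0.5) add += 0.5 * obs(i, 5);   // BLQ: inflate additive SD
    double s2 = prop * prop * p * p + add * add;
    if (!(s2 > 0.0) || !R_finite(s2)) return 1e10;
    double r = obs(i, 2) - p;
    ll += std::log(2.0 * M_PI * s2) + r * r / s2;
  }
  return ll;
}

static double prior_ll(const double *eta, const double *om,
                       const int *active) {
  double ll = 0.0;
  for (int j = 0; j < 29; ++j) {
    if (!active[j]) continue;
    double w = omega_for(j, om);
    ll += std::log(2.0 * M_PI * w * w) + eta[j] * eta[j] / (w * w);
  }
  return ll;
}

static double neg2lj_core(const double *eta, const NumericMatrix &obs,
                          const NumericMatrix &vis, const NumericMatrix &vispars,
                          const double *errw, const double *om,
                          const int *active) {
  int nobs = obs.nrow();
  std::vector<double> pred(nobs, 0.0);
  subject_pred_core(eta, obs, vis, vispars, pred.data());
  double ll = resid_ll_rows(pred.data(), obs, errw, -1) +
    prior_ll(eta, om, active);
  if (!R_finite(ll)) return 1e10;
  return ll;
}

// visit affected by eta index (1-based slot j+1); 0 = all visits
static int visit_of_eta(int k /* 0-based */) {
  if (k == 0) return 0;
  if (k <= 4) return k;
  return (k - 5) / 6 + 1;
}

static void fill_eta(double *eta, const NumericVector &eta_act,
                     const IntegerVector &act_idx) {
  for (int j = 0; j < 29; ++j) eta[j] = 0.0;
  for (int j = 0; j < act_idx.size(); ++j) eta[act_idx[j] - 1] = eta_act[j];
}

static void act_mask(int *active, const IntegerVector &act_idx) {
  for (int j = 0; j < 29; ++j) active[j] = 0;
  for (int j = 0; j < act_idx.size(); ++j) active[act_idx[j] - 1] = 1;
}

// [[Rcpp::export]]
double cpp_subject_neg2lj(NumericVector eta_act, IntegerVector act_idx,
                          NumericMatrix obs, NumericMatrix vis,
                          NumericMatrix vispars, NumericVector errw,
                          NumericVector om) {
  double eta[29]; int active[29];
  fill_eta(eta, eta_act, act_idx);
  act_mask(active, act_idx);
  return neg2lj_core(eta, obs, vis, vispars, REAL(errw), REAL(om), active);
}

// Central finite-difference gradient over the active etas.  The residual
// part of the objective is visit-separable: an occasion or visit eta only
// perturbs its own visit's predictions, so only that visit's likelihood
// piece is recomputed (the prior derivative is analytic).  The subject-level
// eta (index 1) touches every visit.
// [[Rcpp::export]]
NumericVector cpp_subject_grad(NumericVector eta_act, IntegerVector act_idx,
                               NumericMatrix obs, NumericMatrix vis,
                               NumericMatrix vispars, NumericVector errw,
                               NumericVector om, double h) {
  double eta[29]; int active[29];
  fill_eta(eta, eta_act, act_idx);
  act_mask(active, act_idx);
  int d = act_idx.size();
  int nobs = obs.nrow();
  NumericVector g(d);
  std::vector<double> pred(nobs, 0.0);
  for (int j = 0; j < d; ++j) {
    int k = act_idx[j] - 1;
    int v = visit_of_eta(k);
    double e0 = eta[k], fp, fm;
    if (v == 0) {
      eta[k] = e0 + h;
      subject_pred_core(eta, obs, vis, vispars, pred.data());
      fp = resid_ll_rows(pred.data(), obs, REAL(errw), -1);
      eta[k] = e0 - h;
      subject_pred_core(eta, obs, vis, vispars, pred.data());
      fm = resid_ll_rows(pred.data(), obs, REAL(errw), -1);
    } else {
      eta[k] = e0 + h;
      visit_pred_core(eta, obs, vis, vispars, v, pred.data());
      fp = resid_ll_rows(pred.data(), obs, REAL(errw), v);
      eta[k] = e0 - h;
      visit_pred_core(eta, obs, vis, vispars, v, pred.data());
      fm = resid_ll_rows(pred.data(), obs, REAL(errw), v);
    }
    eta[k] = e0;
    if (v != 0) visit_pred_core(eta, obs, vis, vispars, v, pred.data());
    double w = omega_for(k, REAL(om));
    g[j] = (fp - fm) / (2.0 * h) + 2.0 * e0 / (w * w);
  }
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_subject_pred(NumericVector eta_act, IntegerVector act_idx,
                               NumericMatrix obs, NumericMatrix vis,
                               NumericMatrix vispars) {
  double eta[29];
  fill_eta(eta, eta_act, act_idx);
  int nobs = obs.nrow();
  NumericVector pred(nobs);
  subject_pred_core(eta, obs, vis, vispars, REAL(pred));
  return pred;
}

// Jacobian of predictions wrt active etas (central differences, visit-local
// updates for visit/occasion etas).
// [[Rcpp::export]]
NumericMatrix cpp_subject_jac(NumericVector eta_act, IntegerVector act_idx,
                              NumericMatrix obs, NumericMatrix vis,
                              NumericMatrix vispars, double h) {
  double eta[29];
  fill_eta(eta, eta_act, act_idx);
  int nobs = obs.nrow(), d = act_idx.size();
  NumericMatrix J(nobs, d);
  std::vector<double> fp(nobs, 0.0), fm(nobs, 0.0);
  for (int j = 0; j < d; ++j) {
    int k = act_idx[j] - 1;
    int v = visit_of_eta(k);
    double e0 = eta[k];
    if (v == 0) {
      eta[k] = e0 + h;
      subject_pred_core(eta, obs, vis, vispars, fp.data());
      eta[k] = e0 - h;
      subject_pred_core(eta, obs, vis, vispars, fm.data());
      eta[k] = e0;
      for (int i = 0; i < nobs; ++i) J(i, j) = (fp[i] - fm[i]) / (2.0 * h);
    } else {
      eta[k] = e0 + h;
      visit_pred_core(eta, obs, vis, vispars, v, fp.data());
      eta[k] = e0 - h;
      visit_pred_core(eta, obs, vis, vispars, v, fm.data());
      eta[k] = e0;
      for (int i = 0; i < nobs; ++i)
        if ((int)obs(i, 0) == v) J(i, j) = (fp[i] - fm[i]) / (2.0 * h);
    }
  }
  return J;
}
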