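#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs for the two-stage screening model.
//
// Coordinates live on an unconstrained scale:
//  - prevalence, sensitivities, specificities: logit over (0,1); uniform /
//    two-step prior support is enforced by rejection (prior density -Inf
//    outside), so proposals never need a moving support;
//  - conditional covariances: cov = u * bound(accuracies) with u in (0,1),
//    logit-transformed. The conditionally uniform prior on cov is exactly
//    flat in u, so the range-dependent normalization cancels with the
//    Jacobian and u needs no prior term;
//  - latent upper bounds of two-step priors: logit over the fixed
//    hyperprior range (b1, b2); the constraint b > parameter is enforced by
//    rejection.

static inline double inv_logit(double z) {
  if (z > 0) { double e = std::exp(-z); return 1.0 / (1.0 + e); }
  double e = std::exp(z); return e / (1.0 + e);
}

struct ModelState {
  double th[5];   // pi, se1, se2, sp1, sp2
  double u[2];    // covDp, covDn as fractions of their bounds
  double b[5];    // latent upper bounds (two-step priors only)
};

struct Problem {
  double x[4], a[3];         // observed counts
  double lgconst;            // count-dependent log-factorial constants
  int ptype[5];              // 0 = uniform, 1 = two-step
  double p1[5], p2[5], p3[5];// uniform: lower, upper, -; two-step: a, b1, b2
  bool dependence;
  int factorization;         // 0 = two-multinomial, 1 = exact split
};

static inline double cov_bound(double pa, double pb) {
  return std::min(pa, pb) - pa * pb;
}

// log-likelihood of the observed counts (constants included via lgconst)
static double loglik(const Problem& pr, const ModelState& s) {
  const double pi = s.th[0], se1 = s.th[1], se2 = s.th[2],
               sp1 = s.th[3], sp2 = s.th[4];
  const double covDp = pr.dependence ? s.u[0] * cov_bound(se1, se2) : 0.0;
  const double covDn = pr.dependence ? s.u[1] * cov_bound(sp1, sp2) : 0.0;
  double px[4], pa[3];
  px[0] = pi * (se1 * se2 + covDp) + (1 - pi) * ((1 - sp1) * (1 - sp2) + covDn);
  px[1] = pi * (se1 * (1 - se2) - covDp) + (1 - pi) * ((1 - sp1) * sp2 - covDn);
  px[2] = pi * ((1 - se1) * se2 - covDp) + (1 - pi) * (sp1 * (1 - sp2) - covDn);
  px[3] = pi * ((1 - se1) * (1 - se2) + covDp) + (1 - pi) * (sp1 * sp2 + covDn);
  const double seJE = se1 + se2 - (se1 * se2 + covDp);
  const double spJE = sp1 * sp2 + covDn;
  pa[0] = pi * seJE;
  pa[1] = (1 - pi) * (1 - spJE);
  pa[2] = pi * (1 - seJE) + (1 - pi) * spJE;

  double ll = pr.lgconst;
  for (int k = 0; k < 4; ++k) {
    if (pr.x[k] > 0) {
      if (px[k] <= 0) return R_NegInf;
      ll += pr.x[k] * std::log(px[k]);
    }
  }
  if (pr.factorization == 0) {
    for (int k = 0; k < 3; ++k) {
      if (pr.a[k] > 0) {
        if (pa[k] <= 0) return R_NegInf;
        ll += pr.a[k] * std::log(pa[k]);
      }
    }
  } else {
    const double denom = pa[0] + pa[1];
    if (denom <= 0) return R_NegInf;
    const double psplit = pa[0] / denom;
    if (pr.a[0] > 0) { if (psplit <= 0) return R_NegInf; ll += pr.a[0] * std::log(psplit); }
    if (pr.a[1] > 0) { if (psplit >= 1) return R_NegInf; ll += pr.a[1] * std::log(1 - psplit); }
  }
  return ll;
}

// log prior of the base parameters and latent bounds (u's are flat)
static double logprior(const Problem& pr, const ModelState& s) {
  double lp = 0.0;
  for (int i = 0; i < 5; ++i) {
    if (pr.ptype[i] == 0) {
      if (s.th[i] <= pr.p1[i] || s.th[i] >= pr.p2[i]) return R_NegInf;
      lp -= std::log(pr.p2[i] - pr.p1[i]);
    } else {
      if (s.th[i] <= pr.p1[i] || s.th[i] >= s.b[i]) return R_NegInf;
      lp -= std::log(pr.p3[i] - pr.p2[i]) + std::log(s.b[i] - pr.p1[i]);
    }
  }
  return lp;
}

// full log target in z-space (likelihood + prior + transform Jacobians)
static double logpost(const Problem& pr, const ModelState& s) {
  double lp = logprior(pr, s);
  if (!R_FINITE(lp)) return R_NegInf;
  double ll = loglik(pr, s);
  if (!R_FINITE(ll)) return R_NegInf;
  double jac = 0.0;
  for (int i = 0; i < 5; ++i) jac += std::log(s.th[i]) + std::log(1 - s.th[i]);
  if (pr.dependence)
    for (int k = 0; k < 2; ++k) jac += std::log(s.u[k]) + std::log(1 - s.u[k]);
  for (int i = 0; i < 5; ++i)
    if (pr.ptype[i] == 1)
      jac += std::log(s.b[i] - pr.p2[i]) + std::log(pr.p3[i] - s.b[i]);
  return ll + lp + jac;
}

static void decode(const Problem& pr, const std::vector<double>& z,
                   const std::vector<int>& kind, const std::vector<int>& idx,
                   ModelState& s) {
  for (size_t j = 0; j < z.size(); ++j) {
    const double v = inv_logit(z[j]);
    if (kind[j] == 0) s.th[idx[j]] = v;
    else if (kind[j] == 1) s.u[idx[j]] = v;
    else s.b[idx[j]] = pr.p2[idx[j]] + (pr.p3[idx[j]] - pr.p2[idx[j]]) * v;
  }
}

// [[Rcpp::export(name = ".sampler_run")]]
List sampler_run(NumericVector x, NumericVector a,
                 IntegerVector prior_type, NumericVector prior_p1,
                 NumericVector prior_p2, NumericVector prior_p3,
                 bool dependence, int factorization,
                 int n_iter, int n_burnin, int thin,
                 NumericVector init_th, NumericVector init_u,
                 NumericVector init_b) {
  Problem pr;
  double lg = 0.0, nx = 0.0, na = 0.0;
  for (int k = 0; k < 4; ++k) { pr.x[k] = x[k]; nx += x[k]; lg -= std::lgamma(x[k] + 1.0); }
  lg += std::lgamma(nx + 1.0);
  pr.factorization = factorization;
  if (factorization == 0) {
    for (int k = 0; k < 3; ++k) { pr.a[k] = a[k]; na += a[k]; lg -= std::lgamma(a[k] + 1.0); }
    lg += std::lgamma(na + 1.0);
  } else {
    for (int k = 0; k < 3; ++k) pr.a[k] = a[k];
    lg += std::lgamma(a[0] + a[1] + 1.0) - std::lgamma(a[0] + 1.0) - std::lgamma(a[1] + 1.0);
  }
  pr.lgconst = lg;
  pr.dependence = dependence;
  for (int i = 0; i < 5; ++i) {
    pr.ptype[i] = prior_type[i];
    pr.p1[i] = prior_p1[i]; pr.p2[i] = prior_p2[i]; pr.p3[i] = prior_p3[i];
  }

  // coordinate layout
  std::vector<int> kind, idx;
  for (int i = 0; i < 5; ++i) { kind.push_back(0); idx.push_back(i); }
  if (dependence) for (int k = 0; k < 2; ++k) { kind.push_back(1); idx.push_back(k); }
  for (int i = 0; i < 5; ++i)
    if (pr.ptype[i] == 1) { kind.push_back(2); idx.push_back(i); }
  const int nc = (int) kind.size();

  ModelState s;
  for (int i = 0; i < 5; ++i) { s.th[i] = init_th[i]; s.b[i] = NA_REAL; }
  for (int k = 0; k < 2; ++k) s.u[k] = dependence ? init_u[k] : 0.0;
  std::vector<double> z(nc);
  for (int j = 0; j < nc; ++j) {
    double v;
    if (kind[j] == 0) v = init_th[idx[j]];
    else if (kind[j] == 1) v = init_u[idx[j]];
    else {
      s.b[idx[j]] = init_b[idx[j]];
      v = (init_b[idx[j]] - pr.p2[idx[j]]) / (pr.p3[idx[j]] - pr.p2[idx[j]]);
    }
    v = std::min(std::max(v, 1e-12), 1.0 - 1e-12);
    z[j] = std::log(v / (1.0 - v));
  }
  decode(pr, z, kind, idx, s);

  double lp_cur = logpost(pr, s);
  if (!R_FINITE(lp_cur)) stop("initial values have zero posterior density");

  std::vector<double> lsig(nc, std::log(0.5));
  std::vector<int> batch_acc(nc, 0);
  std::vector<long> acc(nc, 0), att(nc, 0);
  const int batch_size = 50;
  int batch_no = 0;

  const int n_keep = (n_iter - n_burnin + thin - 1) / thin;
  NumericMatrix out(n_keep, 13);
  int row = 0;

  RNGScope scope;
  ModelState s_prop;
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < nc; ++j) {
      const double z_old = z[j];
      z[j] = z_old + std::exp(lsig[j]) * norm_rand();
      s_prop = s;
      decode(pr, z, kind, idx, s_prop);
      const double lp_new = logpost(pr, s_prop);
      bool accept = R_FINITE(lp_new) &&
        (lp_new - lp_cur >= 0 || unif_rand() < std::exp(lp_new - lp_cur));
      if (accept) { s = s_prop; lp_cur = lp_new; }
      else z[j] = z_old;
      if (it < n_burnin) { if (accept) ++batch_acc[j]; }
      else { ++att[j]; if (accept) ++acc[j]; }
    }
    // Robbins-Monro scale adaptation toward 0.44 acceptance, burn-in only
    if (it < n_burnin && (it + 1) % batch_size == 0) {
      ++batch_no;
      const double delta = std::min(0.05, 1.0 / std::sqrt((double) batch_no));
      for (int j = 0; j < nc; ++j) {
        lsig[j] += (batch_acc[j] > 0.44 * batch_size) ? delta : -delta;
        batch_acc[j] = 0;
      }
    }
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      const double bDp = cov_bound(s.th[1], s.th[2]);
      const double bDn = cov_bound(s.th[3], s.th[4]);
      out(row, 0) = s.th[0]; out(row, 1) = s.th[1]; out(row, 2) = s.th[2];
      out(row, 3) = s.th[3]; out(row, 4) = s.th[4];
      out(row, 5) = dependence ? s.u[0] * bDp : 0.0;
      out(row, 6) = dependence ? s.u[1] * bDn : 0.0;
      for (int i = 0; i < 5; ++i)
        out(row, 7 + i) = pr.ptype[i] == 1 ? s.b[i] : NA_REAL;
      out(row, 12) = loglik(pr, s);
      ++row;
    }
  }

  NumericVector acc_rate(nc);
  for (int j = 0; j < nc; ++j)
    acc_rate[j] = att[j] > 0 ? (double) acc[j] / att[j] : NA_REAL;
  return List::create(_["draws"] = out, _["acceptance"] = acc_rate,
                      _["n_coord"] = nc);
}
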