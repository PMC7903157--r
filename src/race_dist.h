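// Shared ex-Gaussian / race-model kernels used by the likelihood and the
// Metropolis-within-Gibbs sampler. All in the log domain; log-Phi uses erfc
// with an asymptotic series in the far lower tail.
#ifndef STOPVAR_RACE_DIST_H
#define STOPVAR_RACE_DIST_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

namespace stopvar {

static const double LOG_SQRT_2PI_ = 0.9189385332046727;

static inline double log_phi(double z) {
  if (z < -8.0) {
    double z2 = z * z;
    return -0.5 * z2 - std::log(-z) - LOG_SQRT_2PI_ +
           log1p(-1.0 / z2 + 3.0 / (z2 * z2) - 15.0 / (z2 * z2 * z2) +
                 105.0 / (z2 * z2 * z2 * z2));
  }
  return std::log(0.5 * std::erfc(-z * M_SQRT1_2));
}

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = (a > b) ? a : b;
  return m + log1p(std::exp(-std::fabs(a - b)));
}

// log density of the ex-Gaussian at t
static inline double exg_lpdf(double t, double mu, double sigma, double tau) {
  double z = (t - mu) / sigma;
  return -std::log(tau) + (mu - t) / tau + sigma * sigma / (2.0 * tau * tau) +
         log_phi(z - sigma / tau);
}

// log survival (1 - CDF) of the ex-Gaussian at t
static inline double exg_lsurv(double t, double mu, double sigma, double tau) {
  double z = (t - mu) / sigma;
  double la = log_phi(-z);
  double lb = (mu - t) / tau + sigma * sigma / (2.0 * tau * tau) +
              log_phi(z - sigma / tau);
  double ls = logsumexp2(la, lb);
  return (ls > 0.0) ? 0.0 : ls;
}

// log \int f_stop(s) S_go(d + s) ds by two-panel Gauss-Legendre quadrature
// (Gaussian core + exponential tail; windows hold all but <1e-8 of the mass)
static inline double log_int_stop_win(double d, double mu_go, double sigma_go,
                                      double tau_go, double mu_stop,
                                      double sigma_stop, double tau_stop,
                                      const double* nodes,
                                      const double* weights, int m) {
  double lo = mu_stop - 6.2 * sigma_stop;
  double cut = mu_stop + 4.0 * sigma_stop;
  double hi = cut + 2.2 * sigma_stop + 18.5 * tau_stop;
  double lmax = R_NegInf;
  std::vector<double> lterm(2 * m);
  for (int p = 0; p < 2; ++p) {
    double a = (p == 0) ? lo : cut;
    double b = (p == 0) ? cut : hi;
    double half = 0.5 * (b - a), mid = 0.5 * (a + b);
    for (int j = 0; j < m; ++j) {
      double s = mid + half * nodes[j];
      double lt = std::log(half) +
                  exg_lpdf(s, mu_stop, sigma_stop, tau_stop) +
                  exg_lsurv(d + s, mu_go, sigma_go, tau_go);
      lterm[p * m + j] = lt;
      if (lt > lmax) lmax = lt;
    }
  }
  if (lmax == R_NegInf) return R_NegInf;
  double acc = 0.0;
  for (int p = 0; p < 2; ++p)
    for (int j = 0; j < m; ++j)
      acc += weights[j] * std::exp(lterm[p * m + j] - lmax);
  if (acc <= 0.0) return R_NegInf;
  return lmax + std::log(acc);
}

// per-subject trial data, condensed for likelihood evaluation
struct SubjData {
  std::vector<double> go_rt, sr_rt, sr_ssd, succ_ssd;
  std::vector<int> succ_n;
  int n_cens;
  double max_rt;
};

// go-trial likelihood part (depends on go parameters only); par holds
// (mu_go, sigma_go, tau_go, mu_stop, sigma_stop, tau_stop, p_tf)
static inline double go_loglik(const double* par, const SubjData& d) {
  if (par[1] <= 0 || par[2] <= 0) return R_NegInf;
  double ll = 0.0;
  for (size_t i = 0; i < d.go_rt.size(); ++i)
    ll += exg_lpdf(d.go_rt[i], par[0], par[1], par[2]);
  if (d.n_cens > 0)
    ll += d.n_cens * exg_lsurv(d.max_rt, par[0], par[1], par[2]);
  if (!std::isfinite(ll) && ll != R_NegInf) return R_NegInf;
  return ll;
}

// stop-trial likelihood part (depends on all parameters)
static inline double stop_loglik(const double* par, const SubjData& d,
                                 const double* gx, const double* gw, int m) {
  if (par[1] <= 0 || par[2] <= 0 || par[4] <= 0 || par[5] <= 0 ||
      par[6] < 0 || par[6] > 1)
    return R_NegInf;
  double p_tf = par[6];
  double l_ptf = (p_tf > 0.0) ? std::log(p_tf) : R_NegInf;
  double l_1mptf = (p_tf < 1.0) ? log1p(-p_tf) : R_NegInf;
  double ll = 0.0;
  for (size_t i = 0; i < d.sr_rt.size(); ++i) {
    double lg = exg_lpdf(d.sr_rt[i], par[0], par[1], par[2]);
    double ls = exg_lsurv(d.sr_rt[i] - d.sr_ssd[i], par[3], par[4], par[5]);
    ll += lg + logsumexp2(l_ptf, l_1mptf + ls);
  }
  if (!d.succ_ssd.empty()) {
    if (p_tf >= 1.0) return R_NegInf;
    for (size_t i = 0; i < d.succ_ssd.size(); ++i)
      ll += d.succ_n[i] *
            (l_1mptf + log_int_stop_win(d.succ_ssd[i], par[0], par[1],
                                        par[2], par[3], par[4], par[5],
                                        gx, gw, m));
  }
  if (!std::isfinite(ll) && ll != R_NegInf) return R_NegInf;
  return ll;
}

}  // namespace stopvar

#endif
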