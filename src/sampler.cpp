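// One chain of the adaptive Metropolis-within-Gibbs sampler for the
// hierarchical ex-Gaussian race model. Subject parameters follow truncated
// Normal population distributions (trigger failure on the probit scale).
//
// Moves per iteration:
//   * subject-level multivariate block proposals (go block on alternate
//     sweeps, stop block every sweep) with Haario-style covariance
//     adaptation seeded by a component-wise phase early in burn-in;
//   * group-level location and scale random walks;
//   * joint shift (location + all subject values) and stretch (scale + all
//     subject deviations, Jacobian c^(S+1)) moves for the weakly
//     identified stop-side parameters, alternating across iterations.
// Proposal scales adapt in batches of 25 during burn-in and are frozen
// afterwards. R's RNG is used throughout, so chains are reproducible from
// set.seed() on the R side.

#include <Rcpp.h>
#include "race_dist.h"
using namespace Rcpp;
using namespace stopvar;

static inline double ldtnorm1(double x, double loc, double scale, double lo,
                              double hi) {
  double z = R::pnorm(hi, loc, scale, 1, 0) - R::pnorm(lo, loc, scale, 1, 0);
  return R::dnorm(x, loc, scale, 1) - std::log(z);
}

// lower-triangular Cholesky of a small SPD matrix; false if not SPD
static bool chol_lower(const std::vector<double>& A, int n,
                       std::vector<double>& L) {
  L.assign(n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * n + j];
      for (int k = 0; k < j; ++k) s -= L[i * n + k] * L[j * n + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * n + i] = std::sqrt(s);
      } else {
        L[i * n + j] = s / L[j * n + j];
      }
    }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_fit_chain(List dat_list, NumericMatrix th0, NumericVector loc0,
                   NumericVector scale0, NumericVector prior_lo,
                   NumericVector prior_hi, NumericVector prior_scale_lo,
                   NumericVector prior_scale_hi, int n_samples, int n_burn,
                   int thin, bool estimate_tf, NumericVector gl_x,
                   NumericVector gl_w) {
  const int S = th0.nrow();
  const int P = 7;
  const int n_active = estimate_tf ? 7 : 6;
  const int m = gl_x.size();
  const double* gx = gl_x.begin();
  const double* gw = gl_w.begin();

  std::vector<SubjData> dat(S);
  for (int s = 0; s < S; ++s) {
    List d = dat_list[s];
    NumericVector go_rt = d["go_rt"], sr_rt = d["sr_rt"],
                  sr_ssd = d["sr_ssd"], succ_ssd = d["succ_ssd"];
    IntegerVector succ_n = d["succ_n"];
    dat[s].go_rt.assign(go_rt.begin(), go_rt.end());
    dat[s].sr_rt.assign(sr_rt.begin(), sr_rt.end());
    dat[s].sr_ssd.assign(sr_ssd.begin(), sr_ssd.end());
    dat[s].succ_ssd.assign(succ_ssd.begin(), succ_ssd.end());
    dat[s].succ_n.assign(succ_n.begin(), succ_n.end());
    dat[s].n_cens = as<int>(d["n_go_censored"]);
    dat[s].max_rt = as<double>(d["max_rt"]);
  }

  // state
  std::vector<double> th(S * P), loc(P), scale(P);
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < P; ++k) th[s * P + k] = th0(s, k);
  for (int k = 0; k < P; ++k) { loc[k] = loc0[k]; scale[k] = scale0[k]; }

  auto natpar = [&](const double* row, double* out) {
    for (int k = 0; k < 6; ++k) out[k] = row[k];
    out[6] = R::pnorm(row[6], 0.0, 1.0, 1, 0);
  };
  auto ll_go_f = [&](const double* row, int s) {
    double par[7]; natpar(row, par);
    return go_loglik(par, dat[s]);
  };
  auto ll_stop_f = [&](const double* row, int s) {
    double par[7]; natpar(row, par);
    return stop_loglik(par, dat[s], gx, gw, m);
  };

  std::vector<double> ll_go(S), ll_stop(S);
  for (int s = 0; s < S; ++s) {
    ll_go[s] = ll_go_f(&th[s * P], s);
    ll_stop[s] = ll_stop_f(&th[s * P], s);
    if (!std::isfinite(ll_go[s] + ll_stop[s]))
      stop("non-finite starting likelihood for subject %d", s + 1);
  }

  // blocks: go = {0,1,2}; stop = {3,4,5(,6)}
  const int nb_go = 3;
  const int nb_st = estimate_tf ? 4 : 3;
  const int bsize[2] = {nb_go, nb_st};
  const int boff[2] = {0, 3};

  const double step0[7] = {8, 6, 8, 15, 10, 10, 0.4};
  std::vector<double> step(S * P);
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < P; ++k) step[s * P + k] = step0[k];
  double gstep_loc[7] = {10, 5, 8, 15, 6, 6, 0.3};
  double gstep_scale[7] = {8, 4, 6, 10, 5, 5, 0.25};
  double sstep[7] = {8, 5, 8, 12, 8, 8, 0.3};
  double tstep[7] = {0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2};

  std::vector<int> acc(S * P, 0), try_n(S * P, 0);
  std::vector<int> bacc(S * 2, 0), btry(S * 2, 0);
  int gacc_loc[7] = {0}, gacc_scale[7] = {0}, gtry[7] = {0};
  int sacc[7] = {0}, sacc_try[7] = {0}, tacc[7] = {0}, tacc_try[7] = {0};

  int cw_end = std::max(200, n_burn / 2);
  if (cw_end > n_burn) cw_end = n_burn;

  // running moments for block covariances
  long cov_n = 0;
  std::vector<double> cov_mean(th);
  std::vector<double> cov_m2_go(S * 9, 0.0), cov_m2_st(S * 16, 0.0);
  std::vector<double> lambda(S * 2, 1.0);
  // proposal cholesky factors (lower), initialised diagonal
  std::vector<double> Lgo(S * 9, 0.0), Lst(S * 16, 0.0);
  for (int s = 0; s < S; ++s) {
    for (int k = 0; k < 3; ++k) Lgo[s * 9 + k * 3 + k] = step0[k];
    for (int k = 0; k < nb_st; ++k)
      Lst[s * 16 + k * nb_st + k] = step0[3 + k];
  }

  int n_kept = (n_samples - n_burn) / thin;
  NumericMatrix draws(n_kept, S * P + 2 * P);
  int batch = 0;

  for (int iter = 1; iter <= n_samples; ++iter) {
    if (iter % 500 == 0) Rcpp::checkUserInterrupt();

    if (iter <= cw_end) {
      // phase 1: component-wise random walk
      for (int s = 0; s < S; ++s) {
        for (int k = 0; k < n_active; ++k) {
          try_n[s * P + k]++;
          double cur = th[s * P + k];
          double prop = cur + R::rnorm(0.0, step[s * P + k]);
          if (prop <= prior_lo[k] || prop >= prior_hi[k]) continue;
          double row[7];
          for (int j = 0; j < P; ++j) row[j] = th[s * P + j];
          row[k] = prop;
          double go_new = (k < 3) ? ll_go_f(row, s) : ll_go[s];
          double stop_new = ll_stop_f(row, s);
          double lr = go_new + stop_new - ll_go[s] - ll_stop[s] +
                      ldtnorm1(prop, loc[k], scale[k], prior_lo[k],
                               prior_hi[k]) -
                      ldtnorm1(cur, loc[k], scale[k], prior_lo[k],
                               prior_hi[k]);
          if (std::isfinite(lr) && std::log(R::runif(0.0, 1.0)) < lr) {
            th[s * P + k] = prop;
            ll_go[s] = go_new;
            ll_stop[s] = stop_new;
            acc[s * P + k]++;
          }
        }
      }
    } else {
      // phase 2: multivariate block proposals (go block every 2nd sweep)
      for (int s = 0; s < S; ++s) {
        for (int b = (iter % 2 == 0) ? 0 : 1; b < 2; ++b) {
          int nb = bsize[b], off = boff[b];
          btry[s * 2 + b]++;
          double z[4], dx[4];
          for (int j = 0; j < nb; ++j) z[j] = R::rnorm(0.0, 1.0);
          const double* L = (b == 0) ? &Lgo[s * 9] : &Lst[s * 16];
          double lam = std::sqrt(lambda[s * 2 + b]);
          bool ok = true;
          double row[7];
          for (int j = 0; j < P; ++j) row[j] = th[s * P + j];
          for (int i = 0; i < nb; ++i) {
            dx[i] = 0.0;
            for (int j = 0; j <= i; ++j) dx[i] += L[i * nb + j] * z[j];
            row[off + i] = th[s * P + off + i] + lam * dx[i];
            if (row[off + i] <= prior_lo[off + i] ||
                row[off + i] >= prior_hi[off + i])
              ok = false;
          }
          if (!ok) continue;
          double go_new = (b == 0) ? ll_go_f(row, s) : ll_go[s];
          double stop_new = ll_stop_f(row, s);
          double lr = go_new + stop_new - ll_go[s] - ll_stop[s];
          for (int i = 0; i < nb; ++i) {
            int k = off + i;
            lr += ldtnorm1(row[k], loc[k], scale[k], prior_lo[k],
                           prior_hi[k]) -
                  ldtnorm1(th[s * P + k], loc[k], scale[k], prior_lo[k],
                           prior_hi[k]);
          }
          if (std::isfinite(lr) && std::log(R::runif(0.0, 1.0)) < lr) {
            for (int i = 0; i < nb; ++i) th[s * P + off + i] = row[off + i];
            ll_go[s] = go_new;
            ll_stop[s] = stop_new;
            bacc[s * 2 + b]++;
          }
        }
      }
    }

    // running covariance accumulation during burn-in
    if (iter <= n_burn) {
      cov_n++;
      for (int s = 0; s < S; ++s) {
        double d1[7], d2[7];
        for (int k = 0; k < P; ++k) {
          d1[k] = th[s * P + k] - cov_mean[s * P + k];
          cov_mean[s * P + k] += d1[k] / cov_n;
          d2[k] = th[s * P + k] - cov_mean[s * P + k];
        }
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            cov_m2_go[s * 9 + i * 3 + j] += d1[i] * d2[j];
        for (int i = 0; i < nb_st; ++i)
          for (int j = 0; j < nb_st; ++j)
            cov_m2_st[s * 16 + i * nb_st + j] += d1[3 + i] * d2[3 + j];
      }
    }

    // group-level location and scale random walks
    for (int k = 0; k < n_active; ++k) {
      gtry[k]++;
      double prop = loc[k] + R::rnorm(0.0, gstep_loc[k]);
      if (prop > prior_lo[k] && prop < prior_hi[k]) {
        double lr = 0.0;
        for (int s = 0; s < S; ++s)
          lr += ldtnorm1(th[s * P + k], prop, scale[k], prior_lo[k],
                         prior_hi[k]) -
                ldtnorm1(th[s * P + k], loc[k], scale[k], prior_lo[k],
                         prior_hi[k]);
        if (std::isfinite(lr) && std::log(R::runif(0.0, 1.0)) < lr) {
          loc[k] = prop;
          gacc_loc[k]++;
        }
      }
      prop = scale[k] + R::rnorm(0.0, gstep_scale[k]);
      if (prop > prior_scale_lo[k] && prop < prior_scale_hi[k]) {
        double lr = 0.0;
        for (int s = 0; s < S; ++s)
          lr += ldtnorm1(th[s * P + k], loc[k], prop, prior_lo[k],
                         prior_hi[k]) -
                ldtnorm1(th[s * P + k], loc[k], scale[k], prior_lo[k],
                         prior_hi[k]);
        if (std::isfinite(lr) && std::log(R::runif(0.0, 1.0)) < lr) {
          scale[k] = prop;
          gacc_scale[k]++;
        }
      }
    }

    // joint shift move (stop-side parameters, every 4th iteration)
    if (iter % 4 == 0) {
      for (int k = 3; k < n_active; ++k) {
        sacc_try[k]++;
        double dlt = R::rnorm(0.0, sstep[k]);
        double loc_new = loc[k] + dlt;
        if (loc_new <= prior_lo[k] || loc_new >= prior_hi[k]) continue;
        bool ok = true;
        for (int s = 0; s < S && ok; ++s) {
          double v = th[s * P + k] + dlt;
          if (v <= prior_lo[k] || v >= prior_hi[k]) ok = false;
        }
        if (!ok) continue;
        std::vector<double> stop_new(S);
        double lr = 0.0;
        for (int s = 0; s < S; ++s) {
          double row[7];
          for (int j = 0; j < P; ++j) row[j] = th[s * P + j];
          row[k] += dlt;
          stop_new[s] = ll_stop_f(row, s);
          lr += stop_new[s] - ll_stop[s];
        }
        // Gaussian kernel is shift-invariant; only the truncation
        // normalizer changes
        double zn_old = R::pnorm(prior_hi[k], loc[k], scale[k], 1, 0) -
                        R::pnorm(prior_lo[k], loc[k], scale[k], 1, 0);
        double zn_new = R::pnorm(prior_hi[k], loc_new, scale[k], 1, 0) -
                        R::pnorm(prior_lo[k], loc_new, scale[k], 1, 0);
        lr += S * (std::log(zn_old) - std::log(zn_new));
        if (std::isfinite(lr) && std::log(R::runif(0.0, 1.0)) < lr) {
          loc[k] = loc_new;
          for (int s = 0; s < S; ++s) {
            th[s * P + k] += dlt;
            ll_stop[s] = stop_new[s];
          }
          sacc[k]++;
        }
      }
    }

    // joint stretch move (stop-side parameters, every 4th iteration)
    if (iter % 4 == 2) {
      for (int k = 3; k < n_active; ++k) {
        tacc_try[k]++;
        double lc = R::rnorm(0.0, tstep[k]);
        double cfac = std::exp(lc);
        double scale_new = scale[k] * cfac;
        if (scale_new <= prior_scale_lo[k] || scale_new >= prior_scale_hi[k])
          continue;
        bool ok = true;
        std::vector<double> th_new(S);
        for (int s = 0; s < S && ok; ++s) {
          th_new[s] = loc[k] + cfac * (th[s * P + k] - loc[k]);
          if (th_new[s] <= prior_lo[k] || th_new[s] >= prior_hi[k])
            ok = false;
        }
        if (!ok) continue;
        std::vector<double> stop_new(S);
        double lr = (S + 1) * lc;
        for (int s = 0; s < S; ++s) {
          double row[7];
          for (int j = 0; j < P; ++j) row[j] = th[s * P + j];
          row[k] = th_new[s];
          stop_new[s] = ll_stop_f(row, s);
          lr += stop_new[s] - ll_stop[s];
          lr += ldtnorm1(th_new[s], loc[k], scale_new, prior_lo[k],
                         prior_hi[k]) -
                ldtnorm1(th[s * P + k], loc[k], scale[k], prior_lo[k],
                         prior_hi[k]);
        }
        if (std::isfinite(lr) && std::log(R::runif(0.0, 1.0)) < lr) {
          scale[k] = scale_new;
          for (int s = 0; s < S; ++s) {
            th[s * P + k] = th_new[s];
            ll_stop[s] = stop_new[s];
          }
          tacc[k]++;
        }
      }
    }

    // batchwise adaptation during burn-in, frozen afterwards
    if (iter <= n_burn && iter % 25 == 0) {
      batch++;
      double delta = std::min(0.12, 1.0 / std::sqrt((double)batch));
      if (iter <= cw_end) {
        for (int i = 0; i < S * P; ++i) {
          double rate = try_n[i] > 0 ? (double)acc[i] / try_n[i] : 0.0;
          step[i] *= std::exp(delta * ((rate > 0.35) ? 1.0 : -1.0));
          acc[i] = 0;
          try_n[i] = 0;
        }
      } else {
        for (int i = 0; i < S * 2; ++i) {
          double rate = btry[i] > 0 ? (double)bacc[i] / btry[i] : 0.0;
          lambda[i] *= std::exp(2 * delta * ((rate > 0.28) ? 1.0 : -1.0));
          bacc[i] = 0;
          btry[i] = 0;
        }
        if (cov_n > 50) {
          const double sd0 = 2.38 * 2.38;
          std::vector<double> Sig, L;
          for (int s = 0; s < S; ++s) {
            // go block
            Sig.assign(9, 0.0);
            for (int i = 0; i < 9; ++i)
              Sig[i] = sd0 / 3.0 * cov_m2_go[s * 9 + i] / (cov_n - 1);
            for (int i = 0; i < 3; ++i)
              Sig[i * 3 + i] += 1e-4 * step0[i] * step0[i];
            if (chol_lower(Sig, 3, L))
              std::copy(L.begin(), L.end(), &Lgo[s * 9]);
            // stop block
            Sig.assign(nb_st * nb_st, 0.0);
            for (int i = 0; i < nb_st * nb_st; ++i)
              Sig[i] = sd0 / nb_st * cov_m2_st[s * 16 + i] / (cov_n - 1);
            for (int i = 0; i < nb_st; ++i)
              Sig[i * nb_st + i] += 1e-4 * step0[3 + i] * step0[3 + i];
            if (chol_lower(Sig, nb_st, L))
              std::copy(L.begin(), L.end(), &Lst[s * 16]);
          }
        }
      }
      for (int k = 0; k < P; ++k) {
        double rl = gtry[k] > 0 ? (double)gacc_loc[k] / gtry[k] : 0.0;
        double rs = gtry[k] > 0 ? (double)gacc_scale[k] / gtry[k] : 0.0;
        gstep_loc[k] *= std::exp(delta * ((rl > 0.35) ? 1.0 : -1.0));
        gstep_scale[k] *= std::exp(delta * ((rs > 0.35) ? 1.0 : -1.0));
        gacc_loc[k] = 0;
        gacc_scale[k] = 0;
        gtry[k] = 0;
        double rsh = sacc_try[k] > 0 ? (double)sacc[k] / sacc_try[k] : 0.0;
        sstep[k] *= std::exp(delta * ((rsh > 0.3) ? 1.0 : -1.0));
        sacc[k] = 0;
        sacc_try[k] = 0;
        double rst = tacc_try[k] > 0 ? (double)tacc[k] / tacc_try[k] : 0.0;
        tstep[k] *= std::exp(delta * ((rst > 0.3) ? 1.0 : -1.0));
        tacc[k] = 0;
        tacc_try[k] = 0;
      }
    }

    // store retained draws: subjects (7 each, subject-major), then
    // locations, then scales
    if (iter > n_burn) {
      int rel = iter - n_burn;
      if (rel % thin == 0) {
        int row = rel / thin - 1;
        for (int i = 0; i < S * P; ++i) draws(row, i) = th[i];
        for (int k = 0; k < P; ++k) {
          draws(row, S * P + k) = loc[k];
          draws(row, S * P + P + k) = scale[k];
        }
      }
    }
  }

  NumericMatrix accmat(S, 2);
  for (int s = 0; s < S; ++s)
    for (int b = 0; b < 2; ++b)
      accmat(s, b) =
          btry[s * 2 + b] > 0 ? (double)bacc[s * 2 + b] / btry[s * 2 + b]
                              : NA_REAL;
  return List::create(_["draws"] = draws, _["acceptance"] = accmat);
}
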