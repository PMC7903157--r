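// Exported likelihood entry points for the ex-Gaussian horse-race model
// with trigger failures (kernels in race_dist.h).

#include <Rcpp.h>
#include "race_dist.h"
using namespace Rcpp;
using namespace stopvar;

static SubjData as_subj(NumericVector go_rt, int n_go_censored, double max_rt,
                        NumericVector sr_rt, NumericVector sr_ssd,
                        NumericVector succ_ssd, IntegerVector succ_n) {
  SubjData d;
  d.go_rt.assign(go_rt.begin(), go_rt.end());
  d.sr_rt.assign(sr_rt.begin(), sr_rt.end());
  d.sr_ssd.assign(sr_ssd.begin(), sr_ssd.end());
  d.succ_ssd.assign(succ_ssd.begin(), succ_ssd.end());
  d.succ_n.assign(succ_n.begin(), succ_n.end());
  d.n_cens = n_go_censored;
  d.max_rt = max_rt;
  return d;
}

// [[Rcpp::export]]
double cpp_stop_success_logp(double ssd, NumericVector par,
                             NumericVector gl_nodes,
                             NumericVector gl_weights) {
  double p_tf = par[6];
  if (p_tf >= 1.0) return R_NegInf;
  return log1p(-p_tf) +
         log_int_stop_win(ssd, par[0], par[1], par[2], par[3], par[4],
                          par[5], gl_nodes.begin(), gl_weights.begin(),
                          gl_nodes.size());
}

// [[Rcpp::export]]
double cpp_go_loglik(NumericVector par, NumericVector go_rt,
                     int n_go_censored, double max_rt) {
  SubjData d;
  d.go_rt.assign(go_rt.begin(), go_rt.end());
  d.n_cens = n_go_censored;
  d.max_rt = max_rt;
  return go_loglik(par.begin(), d);
}

// [[Rcpp::export]]
double cpp_stop_loglik(NumericVector par, NumericVector sr_rt,
                       NumericVector sr_ssd, NumericVector succ_ssd,
                       IntegerVector succ_n, NumericVector gl_nodes,
                       NumericVector gl_weights) {
  SubjData d = as_subj(NumericVector(0), 0, 0.0, sr_rt, sr_ssd, succ_ssd,
                       succ_n);
  return stop_loglik(par.begin(), d, gl_nodes.begin(), gl_weights.begin(),
                     gl_nodes.size());
}

// full session log-likelihood
// par = (mu_go, sigma_go, tau_go, mu_stop, sigma_stop, tau_stop, p_tf)
// [[Rcpp::export]]
double cpp_session_loglik(NumericVector par, NumericVector go_rt,
                          int n_go_censored, double max_rt,
                          NumericVector sr_rt, NumericVector sr_ssd,
                          NumericVector succ_ssd, IntegerVector succ_n,
                          NumericVector gl_nodes, NumericVector gl_weights) {
  SubjData d = as_subj(go_rt, n_go_censored, max_rt, sr_rt, sr_ssd,
                       succ_ssd, succ_n);
  double a = go_loglik(par.begin(), d);
  if (a == R_NegInf) return R_NegInf;
  double b = stop_loglik(par.begin(), d, gl_nodes.begin(),
                         gl_weights.begin(), gl_nodes.size());
  if (b == R_NegInf) return R_NegInf;
  return a + b;
}
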