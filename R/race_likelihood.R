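#' Race-model likelihood of a single trial
#'
#' Likelihood contributions under the independent horse-race model with
#' ex-Gaussian finishing-time distributions and trigger failures:
#' \itemize{
#'   \item go trial with RT `t`: `f_go(t)`;
#'   \item failed stop with RT `t` at SSD `d`:
#'     `f_go(t) * (p_tf + (1 - p_tf) * (1 - F_stop(t - d)))`;
#'   \item successful stop at SSD `d`:
#'     `(1 - p_tf) * integral f_stop(s) (1 - F_go(d + s)) ds`.
#' }
#' The successful-stop integral is evaluated by Gauss-Legendre quadrature on
#' a support window carrying all but less than 1e-8 of the stop-latency
#' mass; all computation is in the log domain.
#'
#' @param trial a one-row data frame with columns `kind`, `ssd`, `response`,
#'   `rt` (as in an `ss_session`'s `trials`).
#' @param params a [race_params()].
#' @return the log-likelihood (a scalar).
#' @seealso [session_loglik()], [stop_success_prob()]
#' @export
trial_loglik <- function(trial, params) {
  stopifnot(inherits(params, "race_params"))
  kind <- trial$kind
  if (kind == "go") {
    if (is.na(trial$rt)) stop("go trial without RT: pass omissions through ",
                              "session_loglik's censoring", call. = FALSE)
    return(dexgauss(trial$rt, params$mu_go, params$sigma_go, params$tau_go,
                    log = TRUE))
  }
  if (is.na(trial$ssd)) stop("stop trial without SSD", call. = FALSE)
  if (trial$response != "none") {
    if (is.na(trial$rt)) stop("responded trial without RT", call. = FALSE)
    lg <- dexgauss(trial$rt, params$mu_go, params$sigma_go, params$tau_go,
                   log = TRUE)
    s_stop <- pexgauss(trial$rt - trial$ssd, params$mu_stop,
                       params$sigma_stop, params$tau_stop,
                       lower.tail = FALSE)
    return(lg + log(params$p_tf + (1 - params$p_tf) * s_stop))
  }
  log(stop_success_prob(trial$ssd, params))
}

#' Probability of a successful stop at a given SSD
#'
#' `(1 - p_tf)` times the probability that the stop runner beats the go
#' runner, `integral f_stop(s) (1 - F_go(d + s)) ds`, by adaptive quadrature.
#'
#' @param ssd stop-signal delay(s), ms (vectorized).
#' @param params a [race_params()].
#' @param abs_tol absolute tolerance of the quadrature.
#' @return probability in `[0, 1]` for each `ssd`.
#' @export
stop_success_prob <- function(ssd, params, abs_tol = 1e-8) {
  stopifnot(inherits(params, "race_params"))
  vapply(ssd, function(d) {
    f <- function(s)
      dexgauss(s, params$mu_stop, params$sigma_stop, params$tau_stop) *
      pexgauss(d + s, params$mu_go, params$sigma_go, params$tau_go,
               lower.tail = FALSE)
    lo <- params$mu_stop - 6.2 * params$sigma_stop
    hi <- params$mu_stop + 6.2 * params$sigma_stop + 18.5 * params$tau_stop
    v <- integrate(f, lo, hi, abs.tol = abs_tol, rel.tol = 1e-10,
                   subdivisions = 500L)$value
    (1 - params$p_tf) * min(1, max(0, v))
  }, numeric(1))
}

# Gauss-Legendre rule on [-1, 1] shared by the compiled likelihood, which
# applies it on two panels (Gaussian core + exponential tail) per integral
gl_rule <- local({
  cache <- NULL
  function(n = 24L) {
    if (is.null(cache)) {
      r <- pracma::gaussLegendre(n, -1, 1)
      cache <<- list(x = r$x, w = r$w)
    }
    cache
  }
})

# condensed per-session data for the compiled likelihood
session_race_data <- function(session, censor_omissions = TRUE) {
  tr <- session$trials
  cond <- trial_condition(session)
  sr <- cond == "stop-fail"
  succ_tab <- table(tr$ssd[cond == "stop-success"])
  list(go_rt = tr$rt[cond == "go-success"],
       n_go_censored = if (censor_omissions) sum(cond == "go-omission") else 0L,
       max_rt = session$design$max_rt,
       sr_rt = tr$rt[sr], sr_ssd = tr$ssd[sr],
       succ_ssd = as.numeric(names(succ_tab)),
       succ_n = as.integer(succ_tab))
}

#' Race-model log-likelihood of a whole session
#'
#' Sums [trial_loglik()] over all trials using the compiled kernel: correct
#' go RTs enter through the go density, go omissions as right-censored at the
#' response deadline, failed stops through the signal-respond density and
#' successful stops through the quadrature inhibition probability.
#' Wrong-direction go responses are excluded.
#'
#' @param session an `ss_session`.
#' @param params a [race_params()].
#' @param censor_omissions include go omissions as right-censored
#'   observations (default `TRUE`).
#' @return the session log-likelihood.
#' @export
session_loglik <- function(session, params, censor_omissions = TRUE) {
  stopifnot(inherits(params, "race_params"))
  check_exgauss_params(params$sigma_go, params$tau_go)
  check_exgauss_params(params$sigma_stop, params$tau_stop)
  dat <- session_race_data(session, censor_omissions)
  gl <- gl_rule()
  cpp_session_loglik(unlist(params[1:7], use.names = FALSE),
                     dat$go_rt, dat$n_go_censored, dat$max_rt,
                     dat$sr_rt, dat$sr_ssd, dat$succ_ssd, dat$succ_n,
                     gl$x, gl$w)
}
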