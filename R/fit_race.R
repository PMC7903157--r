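#' MCMC settings for the hierarchical race-model fit
#'
#' Defaults follow the conventional analysis this package emulates: 3 chains
#' of 30,000 samples with 10,000 burn-in, thinning of 10, 1000 posterior
#' predictions, and trigger-failure estimation switched on. The retained
#' draw count per chain is `(n_samples - n_burn_in) / thinning`.
#'
#' @param n_chains number of chains.
#' @param n_samples total iterations per chain (including burn-in).
#' @param n_burn_in iterations discarded as burn-in (`< n_samples`).
#' @param thinning keep every `thinning`-th post-burn-in draw.
#' @param n_predictions parameter draws used for posterior predictions.
#' @param estimate_trigger_failure estimate `p_tf` (else fixed at 0).
#' @param seed integer RNG seed (chain c uses `seed + c`).
#' @return an `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_chains = 3, n_samples = 30000, n_burn_in = 10000,
                          thinning = 10, n_predictions = 1000,
                          estimate_trigger_failure = TRUE, seed = 1) {
  if (n_samples <= n_burn_in)
    stop("n_samples must exceed n_burn_in", call. = FALSE)
  if (thinning < 1) stop("thinning must be >= 1", call. = FALSE)
  if (n_chains < 1) stop("need at least one chain", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 n_burn_in = as.integer(n_burn_in),
                 thinning = as.integer(thinning),
                 n_predictions = as.integer(n_predictions),
                 estimate_trigger_failure = isTRUE(estimate_trigger_failure),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Priors for the hierarchical race model
#'
#' Subject-level parameters follow truncated-Normal population
#' distributions: the mu's on (0, 2000) ms, the sigma's and tau's on
#' (1, 500) ms, and the trigger-failure probability on the probit scale
#' (support (-6, 2), i.e. p_tf roughly in (1e-9, 0.977)). Group locations
#' have uniform priors over the same supports; group scales are uniform on
#' (0.01, 500) ms (probit scale: (0.01, 3)).
#'
#' @param mu_bounds,sig_tau_bounds,probit_bounds supports of the subject-
#'   level parameters.
#' @param scale_max upper bound of the uniform prior on group scales (ms
#'   parameters).
#' @param probit_scale_max upper bound for the probit-scale group scale.
#' @return a `race_priors` list.
#' @export
race_priors <- function(mu_bounds = c(0, 2000), sig_tau_bounds = c(1, 500),
                        probit_bounds = c(-6, 2), scale_max = 500,
                        probit_scale_max = 3) {
  lo <- c(mu_bounds[1], sig_tau_bounds[1], sig_tau_bounds[1],
          mu_bounds[1], sig_tau_bounds[1], sig_tau_bounds[1],
          probit_bounds[1])
  hi <- c(mu_bounds[2], sig_tau_bounds[2], sig_tau_bounds[2],
          mu_bounds[2], sig_tau_bounds[2], sig_tau_bounds[2],
          probit_bounds[2])
  structure(list(lo = lo, hi = hi,
                 scale_lo = rep(0.01, 7),
                 scale_hi = c(rep(scale_max, 6), probit_scale_max)),
            class = "race_priors")
}

.race_par_names <- c("mu_go", "sigma_go", "tau_go",
                     "mu_stop", "sigma_stop", "tau_stop", "ptf_probit")

# log density of Normal(loc, scale) truncated to (lo, hi), vectorized over x
ldtnorm <- function(x, loc, scale, lo, hi) {
  dnorm(x, loc, scale, log = TRUE) -
    log(pnorm(hi, loc, scale) - pnorm(lo, loc, scale))
}

# crude moment-based starting values for one subject
.init_subject <- function(dat, ssrt_guess) {
  m <- mean(dat$go_rt); s <- sd(dat$go_rt)
  tau0 <- min(max(0.8 * s, 10), 400)
  mu0 <- min(max(m - tau0, 50), 1500)
  sigma0 <- min(max(sqrt(max(s^2 - tau0^2, 225)), 5), 300)
  c(mu0, sigma0, tau0,
    min(max(ssrt_guess - 50, 50), 800), 40, 60, qnorm(0.05))
}

# refine the moment start by a short individual maximum-likelihood search,
# so chains start near the subject's likelihood ridge and burn-in is spent
# on the hierarchical structure rather than on subject-level drift
.init_subject_mle <- function(dat, ssrt_guess, priors, gl, estimate_tf,
                              maxit = 400) {
  x0 <- .init_subject(dat, ssrt_guess)
  idx <- if (estimate_tf) 1:7 else 1:6
  nll <- function(x) {
    th <- x0
    th[idx] <- x
    if (any(th[1:6] <= priors$lo[1:6]) || any(th[1:6] >= priors$hi[1:6]) ||
        th[7] < priors$lo[7] || th[7] > priors$hi[7])
      return(1e10)
    v <- cpp_session_loglik(c(th[1:6], pnorm(th[7])), dat$go_rt,
                            dat$n_go_censored, dat$max_rt, dat$sr_rt,
                            dat$sr_ssd, dat$succ_ssd, dat$succ_n,
                            gl$x, gl$w)
    if (!is.finite(v)) 1e10 else -v
  }
  if (!estimate_tf) x0[7] <- -20
  opt <- tryCatch(
    optim(x0[idx], nll, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-7)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9)
    x0[idx] <- opt$par
  x0
}

#' Fit the hierarchical Bayesian ex-Gaussian race model
#'
#' Estimates the full SSRT distribution (go and stop ex-Gaussian parameters
#' plus trigger-failure probability) for every subject simultaneously with
#' group-level locations and scales, by adaptive Metropolis-within-Gibbs
#' sampling. Subject parameters follow truncated-Normal population
#' distributions (trigger failure on the probit scale); proposal scales are
#' tuned during burn-in toward a 20-50% acceptance rate and frozen
#' afterwards. Groups (e.g. children and adults) are fitted separately: pass
#' one group's sessions per call.
#'
#' @param sessions list of `ss_session` objects (at least 2).
#' @param settings an [mcmc_settings()].
#' @param priors a [race_priors()].
#' @param censor_omissions treat go omissions as right-censored at the
#'   response deadline.
#' @param verbose print progress.
#' @return an object of class `race_fit` with elements `draws` (array
#'   iterations x chains x parameters, post burn-in and thinned), `par_names`,
#'   `subjects`, `group`, `settings`, `priors`, `acceptance` (mean
#'   post-burn-in acceptance rate per parameter block).
#' @seealso [rhat_diagnostics()],
#'   [predict.race_fit()]
#' @export
fit_race <- function(sessions, settings = mcmc_settings(),
                     priors = race_priors(), censor_omissions = TRUE,
                     verbose = FALSE) {
  stopifnot(inherits(settings, "mcmc_settings"),
            inherits(priors, "race_priors"))
  if (length(sessions) < 2)
    stop("hierarchical fit needs at least 2 subjects", call. = FALSE)
  S <- length(sessions)
  ids <- vapply(sessions, function(s) s$subject_id, character(1))
  groups <- unique(vapply(sessions, function(s) s$group, character(1)))
  if (length(groups) > 1)
    warning("sessions span several groups (", paste(groups, collapse = ", "),
            "); groups are normally fitted separately")

  dat <- lapply(sessions, session_race_data, censor_omissions)
  gl <- gl_rule()
  ssrt_guess <- vapply(sessions, function(s)
    tryCatch(compute_ssrt_integration(s), error = function(e) 250),
    numeric(1))

  active <- if (settings$estimate_trigger_failure) 1:7 else 1:6
  n_kept <- (settings$n_samples - settings$n_burn_in) %/% settings$thinning
  par_names <- c(
    as.vector(outer(.race_par_names, ids,
                    function(p, i) paste0(p, "[", i, "]"))),
    paste0(.race_par_names, "_loc"), paste0(.race_par_names, "_scale"))
  n_par <- length(par_names)
  draws <- array(NA_real_, c(n_kept, settings$n_chains, n_par),
                 dimnames = list(NULL, NULL, par_names))
  acc_post <- matrix(0, S, 7)
  n_post <- 0L

  mle_init <- t(vapply(seq_len(S), function(s)
    .init_subject_mle(dat[[s]], ssrt_guess[s], priors, gl,
                      settings$estimate_trigger_failure),
    numeric(7)))

  for (ch in seq_len(settings$n_chains)) {
    set.seed(settings$seed + ch)
    th <- mle_init
    # chain-specific jitter, clipped inside the supports
    th <- th + matrix(rnorm(S * 7, 0, c(10, 4, 8, 15, 6, 8, 0.2)[col(th)]),
                      S, 7)
    th <- pmin(pmax(th, rep(priors$lo + 1e-3, each = S)),
               rep(priors$hi - 1e-3, each = S))
    if (!settings$estimate_trigger_failure) th[, 7] <- -20
    loc <- colMeans(th)
    scale <- pmax(apply(th, 2, sd), c(rep(5, 6), 0.1))
    loc <- pmin(pmax(loc, priors$lo + 1e-3), priors$hi - 1e-3)
    scale <- pmin(pmax(scale, priors$scale_lo + 1e-3),
                  priors$scale_hi - 1e-3)

    res <- cpp_fit_chain(dat, th, loc, scale, priors$lo, priors$hi,
                         priors$scale_lo, priors$scale_hi,
                         settings$n_samples, settings$n_burn_in,
                         settings$thinning,
                         settings$estimate_trigger_failure, gl$x, gl$w)
    draws[, ch, ] <- res$draws
    acc_post <- acc_post + res$acceptance[, c(1, 1, 1, 2, 2, 2, 2)]
    n_post <- n_post + 1L
  }

  structure(list(draws = draws, par_names = par_names, subjects = ids,
                 group = groups, settings = settings, priors = priors,
                 acceptance = acc_post / n_post),
            class = "race_fit")
}

#' @export
print.race_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Hierarchical ex-Gaussian race-model fit (%s)\n",
              paste(x$group, collapse = ", ")))
  cat(sprintf("  %d subjects; %d chains x %d retained draws (thinning %d)\n",
              length(x$subjects), d[2], d[1], x$settings$thinning))
  gl <- coef(x)$group
  cat("  group-level posterior medians:\n")
  cat(sprintf("    go:   mu %.0f, sigma %.0f, tau %.0f ms\n",
              gl["mu_go"], gl["sigma_go"], gl["tau_go"]))
  cat(sprintf("    stop: mu %.0f, sigma %.0f, tau %.0f ms; p_tf %.3f\n",
              gl["mu_stop"], gl["sigma_stop"], gl["tau_stop"], gl["p_tf"]))
  invisible(x)
}

# flatten draws to (iterations * chains) x parameters
.flat_draws <- function(fit) {
  d <- dim(fit$draws)
  m <- matrix(fit$draws, d[1] * d[2], d[3])
  colnames(m) <- fit$par_names
  m
}

#' Posterior point estimates and credible intervals
#'
#' Posterior medians and central 95% credible intervals for all group-level
#' and subject-level parameters, with the trigger-failure probability
#' reported on the probability scale. The subject-level stop-parameter
#' medians (`mu_stop`, `sigma_stop`, `tau_stop`) are the per-subject
#' behavioral-variability measures used downstream in brain-behavior
#' correlations.
#'
#' @param fit a `race_fit`.
#' @param prob credible-interval mass.
#' @return list with data frames `group` (parameter, median, lower, upper)
#'   and `subjects` (subject_id, parameter, median, lower, upper).
#' @export
posterior_summaries <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "race_fit"))
  m <- .flat_draws(fit)
  a <- (1 - prob) / 2
  smry <- function(v) c(median(v), quantile(v, c(a, 1 - a), names = FALSE))
  rows <- lapply(colnames(m), function(p) {
    v <- m[, p]
    if (grepl("^ptf_probit", p) && !grepl("_scale$", p)) v <- pnorm(v)
    s <- smry(v)
    data.frame(parameter = sub("ptf_probit", "p_tf", p, fixed = TRUE),
               median = s[1], lower = s[2], upper = s[3],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  is_sub <- grepl("\\[", tab$parameter)
  subj <- tab[is_sub, ]
  subj$subject_id <- sub("^.*\\[(.*)\\]$", "\\1", subj$parameter)
  subj$parameter <- sub("\\[.*\\]$", "", subj$parameter)
  subj <- subj[, c("subject_id", "parameter", "median", "lower", "upper")]
  rownames(subj) <- rownames(tab) <- NULL
  list(group = tab[!is_sub, ], subjects = subj)
}

#' @export
summary.race_fit <- function(object, prob = 0.95, ...) {
  out <- posterior_summaries(object, prob)
  out$rhat <- rhat_diagnostics(object)
  class(out) <- "summary.race_fit"
  out
}

#' @export
print.summary.race_fit <- function(x, ...) {
  cat("Group-level posterior (median [95% CrI]):\n")
  g <- x$group
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-18s %9.3f  [%8.3f, %8.3f]\n", g$parameter[i],
                g$median[i], g$lower[i], g$upper[i]))
  if (!is.null(x$rhat)) {
    bad <- x$rhat$parameter[x$rhat$flagged]
    cat(sprintf("Max split-Rhat: %.3f", max(x$rhat$rhat, na.rm = TRUE)))
    if (length(bad)) cat(" -- flagged (> 1.1): ",
                         paste(head(bad, 8), collapse = ", "))
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.race_fit <- function(object, ...) {
  ps <- posterior_summaries(object)
  g <- setNames(ps$group$median, ps$group$parameter)
  group <- c(setNames(g[paste0(.race_par_names[1:6], "_loc")],
                      .race_par_names[1:6]),
             p_tf = unname(g["p_tf_loc"]))
  sub <- ps$subjects
  wide <- do.call(cbind, lapply(unique(sub$parameter), function(p)
    setNames(sub$median[sub$parameter == p],
             sub$subject_id[sub$parameter == p])))
  colnames(wide) <- unique(sub$parameter)
  list(group = group, subjects = wide[object$subjects, , drop = FALSE])
}

#' Split-Rhat convergence diagnostics
#'
#' Potential scale reduction factors computed after splitting every chain in
#' half; parameters with Rhat above `threshold` (default 1.1) are flagged.
#'
#' @param fit a `race_fit` (needs at least 2 chains).
#' @param threshold flagging threshold.
#' @return data frame with `parameter`, `rhat`, `flagged`.
#' @export
rhat_diagnostics <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "race_fit"))
  d <- dim(fit$draws)
  if (d[2] < 2) stop("split-Rhat needs at least 2 chains", call. = FALSE)
  half <- d[1] %/% 2
  rhat <- vapply(seq_len(d[3]), function(j) {
    segs <- list()
    for (ch in seq_len(d[2])) {
      segs[[length(segs) + 1]] <- fit$draws[seq_len(half), ch, j]
      segs[[length(segs) + 1]] <- fit$draws[(half + 1):(2 * half), ch, j]
    }
    split_rhat(segs)
  }, numeric(1))
  data.frame(parameter = fit$par_names, rhat = rhat,
             flagged = !is.na(rhat) & rhat > threshold,
             stringsAsFactors = FALSE)
}

# classic potential scale reduction factor over a list of equal-length chains
split_rhat <- function(segs) {
  m <- length(segs); n <- length(segs[[1]])
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) {
    # all segments constant: identical chains converge by definition
    return(if (is.finite(B) && B > 0) Inf else 1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior-predictive SSRT distribution
#'
#' For each of `n_predictions` retained posterior draws, a new subject's
#' stop parameters are drawn from that draw's population distribution
#' (truncated Normal around the group location) and `n_per` SSRTs are
#' simulated from the implied ex-Gaussian. The pooled sample estimates the
#' group's SSRT distribution.
#'
#' @param object a `race_fit`.
#' @param n_predictions number of parameter draws (default from the fit's
#'   settings, conventionally 1000).
#' @param n_per simulated SSRTs per parameter draw.
#' @param seed optional seed.
#' @param ... unused.
#' @return numeric vector of `n_predictions * n_per` simulated SSRTs (ms).
#' @export
predict.race_fit <- function(object, n_predictions = NULL, n_per = 50,
                             seed = NULL, ...) {
  if (is.null(n_predictions)) n_predictions <- object$settings$n_predictions
  if (!is.null(seed)) set.seed(seed)
  m <- .flat_draws(object)
  pick <- sample.int(nrow(m), n_predictions, replace = TRUE)
  pr <- object$priors
  out <- vector("list", n_predictions)
  for (i in seq_len(n_predictions)) {
    row <- m[pick[i], ]
    mu <- rtruncnorm1(1, row["mu_stop_loc"], row["mu_stop_scale"],
                      pr$lo[4], pr$hi[4])
    sig <- rtruncnorm1(1, row["sigma_stop_loc"], row["sigma_stop_scale"],
                       pr$lo[5], pr$hi[5])
    tau <- rtruncnorm1(1, row["tau_stop_loc"], row["tau_stop_scale"],
                       pr$lo[6], pr$hi[6])
    out[[i]] <- rexgauss(n_per, mu, sig, tau)
  }
  unlist(out)
}

#' @export
plot.race_fit <- function(x, type = c("predictive", "trace"),
                          pars = c("mu_stop_loc", "sigma_stop_loc",
                                   "tau_stop_loc"), ...) {
  type <- match.arg(type)
  if (type == "predictive") {
    pred <- predict(x, n_predictions = min(500, x$settings$n_predictions))
    hist(pred, breaks = 60, freq = FALSE, main = "Posterior-predictive SSRT",
         xlab = "SSRT (ms)", col = adjustcolor("steelblue", 0.6),
         border = "white")
  } else {
    old <- par(mfrow = c(length(pars), 1), mar = c(3, 4, 1.5, 1))
    on.exit(par(old))
    for (p in pars) {
      matplot(x$draws[, , p], type = "l", lty = 1, ylab = p,
              xlab = "retained iteration")
    }
  }
  invisible(x)
}
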