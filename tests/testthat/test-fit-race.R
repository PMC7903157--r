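fake_fit <- function(draws, par_names = dimnames(draws)[[3]]) {
  structure(list(draws = draws, par_names = par_names,
                 subjects = character(0),
                 settings = mcmc_settings(n_samples = 200, n_burn_in = 100,
                                          thinning = 1),
                 priors = race_priors()),
            class = "race_fit")
}

test_that("default MCMC settings mirror the conventional analysis", {
  st <- mcmc_settings()
  expect_equal(st$n_chains, 3L)
  expect_equal(st$n_samples, 30000L)
  expect_equal(st$n_burn_in, 10000L)
  expect_equal(st$thinning, 10L)
  expect_equal(st$n_predictions, 1000L)
  expect_true(st$estimate_trigger_failure)
  expect_equal((st$n_samples - st$n_burn_in) %/% st$thinning, 2000L)
  expect_error(mcmc_settings(n_samples = 100, n_burn_in = 200), "exceed")
  expect_error(mcmc_settings(thinning = 0), "thinning")
})

test_that("retained draw counts and dimensions follow the settings", {
  coh <- simulate_cohort(tiny_group_specs(3, 2)["child"],
                         task_design(n_blocks = 1, trials_per_block = 64),
                         seed = 6)
  fit <- fit_race(coh$sessions,
                  mcmc_settings(n_chains = 2, n_samples = 400,
                                n_burn_in = 200, thinning = 4, seed = 1))
  expect_equal(dim(fit$draws), c(50L, 2L, 3 * 7 + 14))
  expect_true(all(is.finite(fit$draws)))
  # support constraints respected in every retained draw
  sig <- fit$draws[, , "sigma_stop[c01]"]
  expect_true(all(sig > 1 & sig < 500))
})

test_that("fits are reproducible from the seed", {
  coh <- simulate_cohort(tiny_group_specs(3, 2)["child"],
                         task_design(n_blocks = 1, trials_per_block = 64),
                         seed = 6)
  st <- mcmc_settings(n_chains = 1, n_samples = 300, n_burn_in = 150,
                      thinning = 3, seed = 44)
  f1 <- fit_race(coh$sessions, st)
  f2 <- fit_race(coh$sessions, st)
  expect_identical(f1$draws, f2$draws)
})

test_that("split-Rhat is 1 for identical chains and large for disjoint ones", {
  set.seed(2)
  base <- rnorm(200)
  same <- array(rep(base, 2), c(200, 2, 1), dimnames = list(NULL, NULL, "x"))
  rh <- rhat_diagnostics(fake_fit(same))
  expect_equal(rh$rhat, 1, tolerance = 0.05)
  apart <- array(c(rnorm(200), rnorm(200) + 50), c(200, 2, 1),
                 dimnames = list(NULL, NULL, "x"))
  rh2 <- rhat_diagnostics(fake_fit(apart))
  expect_gt(rh2$rhat, 1.1)
  expect_true(rh2$flagged)
  one_chain <- array(rnorm(100), c(100, 1, 1),
                     dimnames = list(NULL, NULL, "x"))
  expect_error(rhat_diagnostics(fake_fit(one_chain)), "2 chains")
})

test_that("split-Rhat matches a direct implementation of the formula", {
  set.seed(5)
  draws <- array(rnorm(400, sd = c(1, 1.4)[rep(1:2, each = 200)]),
                 c(200, 2, 1), dimnames = list(NULL, NULL, "x"))
  rh <- rhat_diagnostics(fake_fit(draws))$rhat
  segs <- list(draws[1:100, 1, 1], draws[101:200, 1, 1],
               draws[1:100, 2, 1], draws[101:200, 2, 1])
  n <- 100
  W <- mean(sapply(segs, var))
  B <- n * var(sapply(segs, mean))
  expect_equal(rh, sqrt(((n - 1) / n * W + B / n) / W), tolerance = 1e-12)
})

test_that("posterior summaries report medians and central intervals", {
  set.seed(3)
  draws <- array(rnorm(600, mean = 7), c(300, 2, 1),
                 dimnames = list(NULL, NULL, "mu_stop_loc"))
  ps <- posterior_summaries(fake_fit(draws))
  v <- as.vector(draws)
  expect_equal(ps$group$median, median(v))
  expect_equal(ps$group$lower, unname(quantile(v, 0.025)))
  expect_equal(ps$group$upper, unname(quantile(v, 0.975)))
  # trigger-failure draws are reported on the probability scale
  pd <- array(qnorm(0.2) + rnorm(600, sd = 1e-6), c(300, 2, 1),
              dimnames = list(NULL, NULL, "ptf_probit_loc"))
  ps2 <- posterior_summaries(fake_fit(pd))
  expect_equal(ps2$group$parameter, "p_tf_loc")
  expect_equal(ps2$group$median, 0.2, tolerance = 1e-5)
})

test_that("posterior predictions pool simulated SSRTs from the posterior", {
  coh <- simulate_cohort(tiny_group_specs(2, 4)["adult"],
                         task_design(), seed = 12)
  fit <- fit_race(coh$sessions,
                  mcmc_settings(n_chains = 1, n_samples = 900,
                                n_burn_in = 400, thinning = 2,
                                estimate_trigger_failure = FALSE,
                                seed = 2))
  pred <- predict(fit, n_predictions = 200, n_per = 40, seed = 1)
  expect_length(pred, 200 * 40)
  ps <- posterior_summaries(fit)$group
  want <- ps$median[ps$parameter == "mu_stop_loc"] +
    ps$median[ps$parameter == "tau_stop_loc"]
  expect_equal(mean(pred), want, tolerance = 0.2 * want)
  # a wider-truth group yields a visibly wider predictive distribution
  wide <- fit
  wide$draws[, , "sigma_stop_loc"] <- fit$draws[, , "sigma_stop_loc"] * 3
  wide$draws[, , "tau_stop_loc"] <- fit$draws[, , "tau_stop_loc"] * 3
  # between-subject mu_stop spread is unchanged, so the widening is
  # attenuated relative to the 3x inflation of sigma and tau
  pw <- predict(wide, n_predictions = 200, n_per = 40, seed = 1)
  expect_gt(IQR(pw), 1.2 * IQR(pred))
})

test_that("subject-level tau estimates track the true tau ordering", {
  # recovery study with wide, realistic individual differences in tau
  scl <- c(mu_go = 40, sigma_go = 10, tau_go = 20, mu_stop = 50,
           sigma_stop = 6, tau_stop = 25, ptf_probit = 0.25)
  specs <- list(child = group_spec(
    16, race_params(450, 60, 120, 210, 45, 55, p_tf = 0), scl))
  coh <- simulate_cohort(specs, task_design(n_blocks = 4), seed = 14,
                         center_groups = TRUE)
  fit <- fit_race(coh$sessions,
                  mcmc_settings(n_chains = 1, n_samples = 3000,
                                n_burn_in = 1300, thinning = 2,
                                estimate_trigger_failure = FALSE,
                                seed = 3))
  cf <- coef(fit)$subjects
  expect_gt(cor(cf[, "tau_stop"], coh$truth$tau_stop), 0.7)
})

test_that("fitting mixed groups warns and tiny inputs error", {
  coh <- simulate_cohort(tiny_group_specs(2, 2),
                         task_design(n_blocks = 1, trials_per_block = 64),
                         seed = 4)
  st <- mcmc_settings(n_chains = 1, n_samples = 120, n_burn_in = 60,
                      thinning = 2, seed = 1)
  expect_warning(fit_race(coh$sessions, st), "separately")
  expect_error(fit_race(coh$sessions[1], st), "2 subjects")
})

test_that("group-level credible intervals cover the truth across datasets", {
  # 20 small simulated cohorts; 95% intervals for the group stop
  # parameters should cover the generating values in >= 85% of cases
  # (Monte-Carlo slack at reduced chain lengths)
  scl <- c(mu_go = 40, sigma_go = 10, tau_go = 20, mu_stop = 50,
           sigma_stop = 6, tau_stop = 12, ptf_probit = 0.25)
  truth <- race_params(440, 60, 110, 215, 45, 45, p_tf = 0)
  target <- c(mu_stop_loc = 215, sigma_stop_loc = 45, tau_stop_loc = 45)
  covered <- 0L
  for (seed in 1:20) {
    coh <- simulate_cohort(list(g = group_spec(6, truth, scl)),
                           task_design(), seed = 300 + seed,
                           center_groups = TRUE)
    fit <- fit_race(coh$sessions,
                    mcmc_settings(n_chains = 2, n_samples = 1200,
                                  n_burn_in = 500, thinning = 2,
                                  estimate_trigger_failure = FALSE,
                                  seed = seed))
    g <- posterior_summaries(fit)$group
    for (p in names(target)) {
      row <- g[g$parameter == p, ]
      covered <- covered + (row$lower <= target[[p]] &&
                              target[[p]] <= row$upper)
    }
  }
  expect_gte(covered / 60, 0.85)
})
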