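test_that("race outcomes are exhaustive: P(stop) + P(respond) = 1", {
  for (p_tf in c(0, 0.1, 0.5)) {
    p <- default_params(p_tf = p_tf)
    for (d in c(50, 200, 400)) {
      p_stop <- stop_success_prob(d, p)
      sr_density <- function(t)
        dexgauss(t, p$mu_go, p$sigma_go, p$tau_go) *
          (p$p_tf + (1 - p$p_tf) *
             pexgauss(t - d, p$mu_stop, p$sigma_stop, p$tau_stop,
                      lower.tail = FALSE))
      p_resp <- integrate(sr_density, -2000, 6000, abs.tol = 1e-10,
                          rel.tol = 1e-12)$value
      expect_equal(p_stop + p_resp, 1, tolerance = 1e-6)
    }
  }
})

test_that("successful stopping is nonincreasing in SSD and zero if p_tf=1", {
  p <- default_params()
  probs <- stop_success_prob(seq(0, 600, by = 50), p)
  expect_true(all(diff(probs) <= 1e-12))
  expect_equal(stop_success_prob(200, default_params(p_tf = 1)), 0)
})

test_that("inhibition probability matches a brute-force race simulation", {
  p <- default_params()
  set.seed(31)
  n <- 1e6
  go <- rexgauss(n, p$mu_go, p$sigma_go, p$tau_go)
  stp <- rexgauss(n, p$mu_stop, p$sigma_stop, p$tau_stop)
  mc <- mean(go >= 200 + stp)
  expect_equal(stop_success_prob(200, p), mc, tolerance = 3e-3)
})

test_that("compiled and reference stop-success probabilities agree", {
  gl <- stopvar:::gl_rule()
  for (pars in list(c(200, 30, 50, 0), c(220, 25, 35, 0.05),
                    c(250, 8, 12, 0), c(220, 60, 70, 0.2))) {
    p <- race_params(400, 50, 100, pars[1], pars[2], pars[3],
                     p_tf = pars[4])
    for (d in c(0, 150, 350)) {
      quad <- exp(stopvar:::cpp_stop_success_logp(
        d, unlist(p[1:7], use.names = FALSE), gl$x, gl$w))
      expect_equal(quad, stop_success_prob(d, p), tolerance = 1e-6)
    }
  }
})

test_that("trial log-likelihoods take the stated race forms", {
  p <- default_params(p_tf = 0.1)
  go_trial <- data.frame(kind = "go", ssd = NA_real_, response = "left",
                         rt = 430)
  expect_equal(trial_loglik(go_trial, p),
               dexgauss(430, 400, 50, 100, log = TRUE))
  sr_trial <- data.frame(kind = "stop", ssd = 250, response = "left",
                         rt = 380)
  expect_equal(trial_loglik(sr_trial, p),
               log(dexgauss(380, 400, 50, 100) *
                     (0.1 + 0.9 * pexgauss(130, 200, 30, 50,
                                           lower.tail = FALSE))))
  succ_trial <- data.frame(kind = "stop", ssd = 250, response = "none",
                           rt = NA_real_)
  expect_equal(trial_loglik(succ_trial, p),
               log(stop_success_prob(250, p)))
  expect_error(trial_loglik(data.frame(kind = "stop", ssd = NA_real_,
                                       response = "none", rt = NA_real_),
                            p), "SSD")
})

test_that("session log-likelihood is additive over trials", {
  s <- fixture_session()
  p <- default_params(p_tf = 0.05)
  cond <- trial_condition(s)
  manual <- 0
  for (i in seq_len(nrow(s$trials))) {
    if (cond[i] == "go-error") next
    if (cond[i] == "go-omission") {
      manual <- manual + pexgauss(1500, p$mu_go, p$sigma_go, p$tau_go,
                                  lower.tail = FALSE, log.p = TRUE)
    } else {
      manual <- manual + trial_loglik(s$trials[i, ], p)
    }
  }
  expect_equal(session_loglik(s, p), manual, tolerance = 1e-6)
})

test_that("generating parameters beat displaced ones on a large session", {
  d <- task_design(n_blocks = 40)
  s <- simulate_session(default_params(), d, seed = 17, go_error_rate = 0)
  truthish <- default_params()
  shifted <- race_params(400, 50, 100, 300, 30, 50)
  expect_gt(session_loglik(s, truthish), session_loglik(s, shifted))
})

test_that("out-of-support parameters are rejected or score -Inf", {
  s <- fixture_session()
  expect_error(session_loglik(s, structure(list(
    mu_go = 400, sigma_go = 0, tau_go = 100, mu_stop = 200,
    sigma_stop = 30, tau_stop = 50, p_tf = 0), class = "race_params")),
    "sigma")
})
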