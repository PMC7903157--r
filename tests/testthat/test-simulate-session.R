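test_that("the SSD staircase moves up after stops and down after responses", {
  s <- fixture_session()
  tr <- s$trials
  st <- which(tr$kind == "stop")
  expect_equal(tr$ssd[st[1]], 250)
  for (i in seq_len(length(st) - 1)) {
    cur <- tr$ssd[st[i]]
    nxt <- tr$ssd[st[i + 1]]
    if (tr$response[st[i]] == "none") {
      expect_equal(nxt, cur + 50)
    } else {
      expect_equal(nxt, max(0, cur - 50))
    }
  }
})

test_that("session structure honors the design invariants", {
  s <- fixture_session()
  tr <- s$trials
  expect_equal(nrow(tr), 256)
  # ssd present iff stop trial; rt present iff responded
  expect_true(all(is.na(tr$ssd[tr$kind == "go"])))
  expect_true(all(!is.na(tr$ssd[tr$kind == "stop"])))
  expect_true(all(is.na(tr$rt[tr$response == "none"])))
  expect_true(all(!is.na(tr$rt[tr$response != "none"])))
  expect_true(all(tr$rt[!is.na(tr$rt)] > 0 &
                    tr$rt[!is.na(tr$rt)] <= 1500))
  # onsets restart per block and advance by max_rt + jittered ITI
  gaps_ms <- diff(tr$onset[tr$block == 1]) * 1000
  expect_true(all(gaps_ms >= 3500 - 1e-6 & gaps_ms <= 5500 + 1e-6))
  expect_lt(tr$onset[which(tr$block == 2)[1]], tr$onset[sum(tr$block == 1)])
})

test_that("p_tf = 1 yields zero successful stops", {
  s <- simulate_session(default_params(p_tf = 1), task_design(), seed = 5)
  st <- s$trials$kind == "stop"
  expect_equal(sum(s$trials$response[st] == "none"), 0)
})

test_that("identical seeds reproduce sessions record-for-record", {
  a <- simulate_session(default_params(), task_design(), seed = 11)
  b <- simulate_session(default_params(), task_design(), seed = 11)
  expect_identical(a$trials, b$trials)
  ca <- simulate_cohort(tiny_group_specs(), task_design(), seed = 3)
  cb <- simulate_cohort(tiny_group_specs(), task_design(), seed = 3)
  expect_identical(ca$truth, cb$truth)
  expect_identical(lapply(ca$sessions, `[[`, "trials"),
                   lapply(cb$sessions, `[[`, "trials"))
})

test_that("default cohort has 19 children and 26 adults with bookkeeping", {
  coh <- simulate_cohort(seed = 2)
  expect_equal(unname(table(coh$truth$group)[c("child", "adult")]),
               c(19L, 26L), ignore_attr = TRUE)
  expect_equal(nrow(coh$truth), length(coh$sessions))
  expect_setequal(coh$truth$subject_id, names(coh$sessions))
  expect_true(all(coh$truth$sigma_stop > 0 & coh$truth$tau_stop > 0))
})

test_that("group centering fixes realized group means at the locations", {
  coh <- simulate_cohort(tiny_group_specs(10, 10), task_design(), seed = 8,
                         center_groups = TRUE)
  for (g in c("child", "adult")) {
    sel <- coh$truth$group == g
    spec <- tiny_group_specs(10, 10)[[g]]
    expect_equal(mean(coh$truth$mu_stop[sel]), spec$loc$mu_stop,
                 tolerance = 1e-10)
    expect_equal(mean(coh$truth$tau_stop[sel]), spec$loc$tau_stop,
                 tolerance = 1e-10)
  }
  # sessions are simulated from the centered parameters
  id <- coh$truth$subject_id[1]
  expect_equal(coh$sessions[[id]]$truth$mu_stop, coh$truth$mu_stop[1])
})

test_that("doubling sigma and tau of the stop process widens true SSRTs", {
  # Monte-Carlo oracle drawing directly from the ex-Gaussian
  set.seed(21)
  narrow <- rexgauss(2e5, 220, 25, 35)
  wide <- rexgauss(2e5, 220, 50, 70)
  expect_gt(sd(wide), 1.9 * sd(narrow))
  expect_gt(quantile(wide, 0.95) - quantile(wide, 0.05),
            quantile(narrow, 0.95) - quantile(narrow, 0.05))
})

test_that("empty or malformed group specs are rejected", {
  expect_error(simulate_cohort(list(), task_design()), "non-empty")
  expect_error(group_spec(0, default_params(), c(mu_go = 1)), "n >= 1")
  expect_error(group_spec(3, default_params(), c(mu_go = 1)), "scale")
})
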