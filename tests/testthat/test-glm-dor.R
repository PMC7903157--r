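toy_run_and_designs <- function(seed = 3) {
  s <- simulate_session(default_params(p_tf = 0.02), task_design(),
                        seed = seed)
  ev <- session_events(s, block = 1)
  n_vol <- floor((max(ev$onset) + 24) / 2.2)
  list(ev = ev, n_vol = n_vol,
       std = build_design(ev, n_vol, 2.2, mode = "standard",
                          conditions = c("go-success", "stop-success")),
       tw = build_design(ev, n_vol, 2.2, mode = "trialwise",
                         conditions = c("go-success", "stop-success")))
}

test_that("per-voxel OLS matches a normal-equations oracle", {
  set.seed(10)
  X <- cbind(1, matrix(rnorm(60 * 3), 60, 3))
  colnames(X) <- c("intercept", "a", "b", "c")
  Y <- matrix(rnorm(5 * 60), 5, 60)
  d <- structure(list(X = X, mode = "standard",
                      condition_of_interest = "a",
                      interest_cols = "a", rank_deficient = FALSE,
                      rank = 4L), class = "design_matrix")
  ssr <- fit_glm_ssr(Y, d)$ssr
  oracle <- apply(Y, 1, function(y) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  })
  expect_equal(ssr, oracle, tolerance = 1e-8)
})

test_that("signals in the design's span have zero residual", {
  td <- toy_run_and_designs()
  beta <- runif(ncol(td$std$X), -1, 1)
  y <- as.numeric(td$std$X %*% beta)
  Y <- rbind(y, 2 * y)
  expect_equal(max(fit_glm_ssr(Y, td$std)$ssr), 0, tolerance = 1e-14)
})

test_that("adding regressors can never increase the residual", {
  td <- toy_run_and_designs()
  set.seed(22)
  Y <- matrix(rnorm(50 * td$n_vol), 50, td$n_vol)
  ssr_std <- fit_glm_ssr(Y, td$std)$ssr
  ssr_tw <- fit_glm_ssr(Y, td$tw)$ssr
  expect_true(all(ssr_tw <= ssr_std + 1e-8))
})

test_that("DoR is zero under zero trial variance and zero noise", {
  td <- toy_run_and_designs()
  spec0 <- bold_sim_spec(amp = default_amp_table(stop_sd = 0,
                                                 calcarine_sd = 0,
                                                 go_sd = 0, err_sd = 0),
                         noise_sd = 0, drift_amp = 0, motion_sd = c(0, 0))
  run0 <- simulate_bold_run(td$ev, spec0, seed = 1)
  dor <- difference_of_residuals(fit_glm_ssr(run0, td$std),
                                 fit_glm_ssr(run0, td$tw))
  expect_equal(max(dor$dor), 0, tolerance = 1e-12)
})

test_that("DoR is nonnegative and grows with the trial-amplitude SD", {
  td <- toy_run_and_designs()
  net <- function(stop_sd, seed) {
    run <- simulate_bold_run(td$ev,
                             bold_sim_spec(amp = default_amp_table(
                               stop_sd = stop_sd)), seed = seed)
    dor <- difference_of_residuals(fit_glm_ssr(run, td$std),
                                   fit_glm_ssr(run, td$tw))
    expect_true(all(dor$dor >= 0))
    extract_roi_values(dor)["network"]
  }
  vals <- sapply(c(0.5, 1, 2), net, seed = 5)
  expect_true(all(diff(vals) > 0))
})

test_that("mismatched residual maps are rejected", {
  td <- toy_run_and_designs()
  set.seed(1)
  Y <- matrix(rnorm(10 * td$n_vol), 10, td$n_vol)
  a <- fit_glm_ssr(Y, td$std)
  b <- fit_glm_ssr(Y, td$tw)
  expect_error(difference_of_residuals(b, a), "standard-mode")
  short <- fit_glm_ssr(Y[1:4, ], td$std)
  expect_error(difference_of_residuals(short, b), "different runs")
})

test_that("fitted trial amplitudes are more variable when simulated so", {
  # regression oracle on noiseless signals: per-trial betas recover the
  # generated amplitudes, so their variance tracks the configured SD
  td <- toy_run_and_designs()
  fit_amp_var <- function(stop_sd, seed) {
    spec <- bold_sim_spec(amp = default_amp_table(stop_sd = stop_sd,
                                                  calcarine_sd = 0,
                                                  go_sd = 0, err_sd = 0),
                          noise_sd = 0, drift_amp = 0,
                          motion_sd = c(0, 0))
    run <- simulate_bold_run(td$ev, spec, seed = seed)
    vox <- which(run$labels == 4)[1]  # one thalamus voxel
    beta <- qr.coef(qr(td$tw$X), run$data[vox, ])
    var(beta[grep("stop-success_trial", names(beta))])
  }
  expect_gt(fit_amp_var(2, 7), 3 * fit_amp_var(0.5, 7))
})

test_that("confound regression leaves residuals orthogonal to confounds", {
  td <- toy_run_and_designs()
  run <- simulate_bold_run(td$ev, bold_sim_spec(), seed = 9)
  den <- denoise(run, confounds = run$motion, outliers = c(5L, 40L))
  cross <- den$data %*% cbind(run$motion, 1)
  expect_lt(max(abs(cross)), 1e-6)
  expect_equal(max(abs(den$data[, 5])), 0, tolerance = 1e-8)
})

test_that("denoising with no confounds just removes the voxel mean", {
  set.seed(2)
  Y <- matrix(rnorm(40, mean = 100), 4, 10)
  out <- denoise(Y)
  expect_equal(out, Y - rowMeans(Y), tolerance = 1e-12)
  expect_error(denoise(Y, outliers = 1:10), "all volumes")
})

test_that("denoising matches a direct OLS oracle", {
  set.seed(6)
  Y <- matrix(rnorm(3 * 30), 3, 30)
  conf <- matrix(rnorm(30 * 2), 30, 2)
  out <- denoise(Y, confounds = conf)
  X <- cbind(1, conf)
  oracle <- t(apply(Y, 1, function(y)
    y - X %*% solve(t(X) %*% X, t(X) %*% y)))
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("framewise displacement follows the backward-difference formula", {
  still <- matrix(0, 10, 6)
  expect_equal(mean_framewise_displacement(still), 0)
  one_step <- still
  one_step[6:10, 1] <- 0.1
  expect_equal(mean_framewise_displacement(one_step), 0.1 / 9)
  # hand-computed 5-volume oracle including rotations
  m <- matrix(0, 5, 6)
  m[2, 1] <- 0.2; m[3, 4] <- 0.002; m[4, 2] <- -0.1
  fd_frames <- c(0.2,                      # x on
                 0.2 + 0.002 * 50,         # x off, rotation on
                 0.002 * 50 + 0.1,         # rotation off, y on
                 0.1)                      # y off
  expect_equal(mean_framewise_displacement(m), mean(fd_frames))
  expect_error(mean_framewise_displacement(matrix(0, 5, 5)), "6 columns")
  expect_error(mean_framewise_displacement(matrix(0, 1, 6)), "2 volumes")
})

test_that("run simulation honors duration, TR and determinism", {
  ev <- data.frame(onset = c(10, 30), duration = 0,
                   trial_type = "stop-success")
  run <- simulate_bold_run(ev, bold_sim_spec(), run_duration = 299.2,
                           seed = 2)
  expect_equal(run$n_volumes, 136)
  run2 <- simulate_bold_run(ev, bold_sim_spec(), run_duration = 299.2,
                            seed = 2)
  expect_identical(run$data, run2$data)
  expect_identical(run$truth, run2$truth)
  expect_error(simulate_bold_run(ev, bold_sim_spec(), run_duration = 20),
               "cover")
  expect_error(bold_sim_spec(tr = 0), "tr")
  expect_error(bold_sim_spec(ar1 = 1.2), "ar1")
  expect_error(bold_sim_spec(noise_sd = -1), "deviations")
})

test_that("noiseless simulation equals the convolved deterministic model", {
  ev <- data.frame(onset = c(12, 47.3), duration = 0,
                   trial_type = "stop-success")
  spec <- bold_sim_spec(amp = default_amp_table(stop_sd = 0,
                                                calcarine_sd = 0,
                                                go_sd = 0, err_sd = 0),
                        noise_sd = 0, drift_amp = 0, motion_sd = c(0, 0))
  run <- simulate_bold_run(ev, spec, run_duration = 200, seed = 4)
  b <- hrf_basis(spec$tr)
  expected <- spec$baseline +
    3 * stopvar:::convolve_events(ev$onset, c(1, 1), c(0, 0), b$hrf, b$dt,
                                  run$n_volumes, spec$tr)
  vox <- which(run$labels == 4)[1]
  expect_equal(run$data[vox, ], expected, tolerance = 1e-10)
  background <- which(run$labels == 0)[1]
  expect_equal(run$data[background, ], rep(spec$baseline, run$n_volumes))
})
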