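test_that("QC keeps sessions at or above the stop-success threshold", {
  expect_false(qc_filter(manual_session(n_success = 29)))
  expect_true(qc_filter(manual_session(n_success = 30)))
  expect_true(qc_filter(manual_session(n_success = 50)))
  expect_equal(attr(qc_filter(manual_session(n_success = 29)),
                    "pct_stop_success"), 29)
  no_stop <- fixture_session()
  no_stop$trials <- no_stop$trials[no_stop$trials$kind == "go", ]
  expect_error(qc_filter(no_stop), "no stop trials")
})

test_that("stopping summaries report counts, rates and means", {
  s <- manual_session(n_stop = 10, n_success = 10)
  out <- summarize_stopping(s, ssrt = FALSE)
  expect_equal(out$pct_stop_success, 100)
  expect_equal(out$n_stop, 10)
  s2 <- manual_session(n_stop = 3, n_success = 1)
  s2$trials$ssd <- c(250, 300, 250)
  out2 <- summarize_stopping(s2, ssrt = FALSE)
  expect_equal(out2$mean_ssd, mean(c(250, 300, 250)))
  sim <- summarize_stopping(fixture_session())
  expect_equal(sim$pct_stop_success, 50, tolerance = 8)
  expect_equal(sim$n_go, 192)
})

test_that("integration SSRT follows the ceil(p*N) rank-order convention", {
  s <- manual_session(n_stop = 10, n_success = 5)
  s$trials$ssd <- 200
  go <- data.frame(index = 11:20, block = 1L, kind = "go",
                   direction = "left", ssd = NA_real_, response = "left",
                   rt = seq(250, 700, by = 50), onset = 60 + 1:10,
                   stringsAsFactors = FALSE)
  s$trials <- rbind(s$trials, go)
  # p = 0.5, N = 10 -> index 5 -> RT 450; minus mean SSD 200 -> 250
  expect_equal(compute_ssrt_integration(s), 250)
})

test_that("degenerate failed-stop proportions are handled explicitly", {
  all_fail <- manual_session(n_stop = 6, n_success = 0)
  all_fail$trials$ssd <- 150
  go <- data.frame(index = 7:9, block = 1L, kind = "go",
                   direction = "left", ssd = NA_real_, response = "left",
                   rt = c(300, 400, 500), onset = 40 + 1:3,
                   stringsAsFactors = FALSE)
  all_fail$trials <- rbind(all_fail$trials, go)
  # p = 1 -> top of the go distribution
  expect_equal(compute_ssrt_integration(all_fail), 500 - 150)
  all_stop <- manual_session(n_stop = 6, n_success = 6)
  expect_error(compute_ssrt_integration(all_stop), "failed stop")
})

test_that("SSRT depends only on the RT multiset, not trial order", {
  s <- fixture_session()
  ref <- compute_ssrt_integration(s)
  set.seed(4)
  perm <- s
  perm$trials <- perm$trials[sample(nrow(perm$trials)), ]
  expect_equal(compute_ssrt_integration(perm), ref)
})

test_that("omission handling can be switched off", {
  s <- fixture_session()
  a <- compute_ssrt_integration(s, omission_rt_max = TRUE)
  b <- compute_ssrt_integration(s, omission_rt_max = FALSE)
  expect_true(is.finite(a) && is.finite(b))
})

test_that("integration SSRT approaches the true mean SSRT on long sessions", {
  # with p_tf = 0 the true mean SSRT is mu_stop + tau_stop = 250
  d <- task_design(n_blocks = 40)
  s <- simulate_session(default_params(), d, seed = 13, go_error_rate = 0)
  expect_equal(compute_ssrt_integration(s), 250, tolerance = 20)
})
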