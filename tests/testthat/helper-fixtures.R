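# shared fixtures, built in code at test time

default_params <- function(p_tf = 0)
  race_params(400, 50, 100, 200, 30, 50, p_tf = p_tf)

fixture_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_session(default_params(), task_design(), seed = 42)
    cache
  }
})

# hand-built session with an exact stop-success percentage, for QC tests
manual_session <- function(n_stop = 100, n_success = 29, max_rt = 1500) {
  n <- n_stop
  trials <- data.frame(
    index = seq_len(n), block = 1L, kind = "stop",
    direction = rep(c("left", "right"), length.out = n),
    ssd = 250, response = "none", rt = NA_real_,
    onset = seq_len(n) * 5, stringsAsFactors = FALSE)
  fail <- seq_len(n - n_success)
  trials$response[fail] <- trials$direction[fail]
  trials$rt[fail] <- 450
  structure(list(subject_id = "m01", group = "adult",
                 design = task_design(max_rt = max_rt), truth = NULL,
                 trials = trials),
            class = "ss_session")
}

tiny_group_specs <- function(n_child = 4, n_adult = 4) {
  scl <- c(mu_go = 40, sigma_go = 10, tau_go = 20, mu_stop = 50,
           sigma_stop = 6, tau_stop = 8, ptf_probit = 0.25)
  list(child = group_spec(n_child,
                          race_params(450, 60, 120, 220, 45, 45, p_tf = 0),
                          scl),
       adult = group_spec(n_adult,
                          race_params(400, 50, 100, 220, 25, 35, p_tf = 0),
                          scl))
}
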