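#' Simulate one participant's stop-signal session
#'
#' Plays the independent horse race trial by trial. On every trial a go
#' finish time is drawn from the go ex-Gaussian; go finish times beyond the
#' response deadline are recorded as omissions. On stop trials the stop
#' process fails to launch with probability `p_tf` (a trigger failure, so the
#' go response is emitted as on a go trial); otherwise a stop latency is
#' drawn from the stop ex-Gaussian and a response is emitted iff the go
#' process finishes before `SSD + stop latency`. The SSD staircase moves up
#' `ssd_step` after every successful stop and down after every failed one
#' (floored at 0), tracking a 50% inhibition rate. A small fraction of
#' responses are emitted with the wrong direction (`go_error_rate`).
#'
#' Trial onsets accumulate the response deadline plus the jittered fixation:
#' because the fixation is extended by `max_rt - RT` after a response, the
#' onset-to-onset interval is `max_rt + ITI` regardless of the outcome.
#'
#' @param params a [race_params()] object (the subject's generating truth).
#' @param design a [task_design()].
#' @param group group label, e.g. `"child"` or `"adult"`.
#' @param subject_id subject identifier.
#' @param seed optional integer seed.
#' @param go_error_rate probability a response is emitted with the wrong
#'   direction.
#' @return an object of class `ss_session`: a list with `subject_id`,
#'   `group`, `design`, `truth` and `trials`, a data frame with one row per
#'   trial (`index`, `block`, `kind`, `direction`, `ssd` in ms (stop trials
#'   only), `response`, `rt` in ms, `onset` in s from the start of the
#'   trial's block).
#' @examples
#' s <- simulate_session(race_params(400, 50, 100, 200, 30, 50),
#'                       task_design(), seed = 1)
#' table(s$trials$kind)
#' @export
simulate_session <- function(params, design, group = "adult",
                             subject_id = "s01", seed = NULL,
                             go_error_rate = 0.02) {
  stopifnot(inherits(params, "race_params"), inherits(design, "task_design"))
  if (!is.null(seed)) set.seed(seed)
  trials <- generate_trial_sequence(design)
  n <- nrow(trials)

  go_finish <- rexgauss(n, params$mu_go, params$sigma_go, params$tau_go)
  go_finish <- pmax(go_finish, 1)  # guard against the exGaussian's left tail
  stop_lat <- rexgauss(n, params$mu_stop, params$sigma_stop, params$tau_stop)
  tf <- runif(n) < params$p_tf
  dir_err <- runif(n) < go_error_rate
  iti <- runif(n, design$iti_jitter[1], design$iti_jitter[2])

  ssd <- rep(NA_real_, n)
  response <- rep("none", n)
  rt <- rep(NA_real_, n)
  onset <- rep(NA_real_, n)

  cur_ssd <- design$ssd_start
  t_cursor <- 2000  # ms lead-in at the start of each block
  cur_block <- trials$block[1]
  for (i in seq_len(n)) {
    if (trials$block[i] != cur_block) {
      cur_block <- trials$block[i]
      t_cursor <- 2000
    }
    onset[i] <- t_cursor / 1000
    gf <- go_finish[i]
    emitted_dir <- if (dir_err[i]) {
      if (trials$direction[i] == "left") "right" else "left"
    } else trials$direction[i]

    if (trials$kind[i] == "go") {
      if (gf <= design$max_rt) {
        response[i] <- emitted_dir
        rt[i] <- gf
      }
    } else {
      ssd[i] <- cur_ssd
      respond <- if (tf[i]) gf <= design$max_rt else
        (gf < cur_ssd + stop_lat[i]) && gf <= design$max_rt
      if (respond) {
        response[i] <- emitted_dir
        rt[i] <- gf
        cur_ssd <- max(0, cur_ssd - design$ssd_step)
      } else {
        cur_ssd <- cur_ssd + design$ssd_step
      }
    }
    t_cursor <- t_cursor + design$max_rt + iti[i]
  }

  trials$ssd <- ssd
  trials$response <- response
  trials$rt <- rt
  trials$onset <- onset
  structure(list(subject_id = subject_id, group = group, design = design,
                 truth = params, trials = trials),
            class = "ss_session")
}

#' @export
print.ss_session <- function(x, ...) {
  tr <- x$trials
  st <- tr$kind == "stop"
  cat(sprintf("Stop-signal session '%s' (%s): %d trials, %d stop\n",
              x$subject_id, x$group, nrow(tr), sum(st)))
  if (any(st))
    cat(sprintf("  successful stops: %.1f%%; final SSD %g ms\n",
                100 * mean(tr$response[st] == "none"),
                tr$ssd[max(which(st))]))
  invisible(x)
}

#' Outcome condition of each trial
#'
#' Classifies trials into `go-success` (correct-direction response),
#' `go-error` (wrong direction), `go-omission`, `stop-success` (no response
#' on a stop trial) and `stop-fail`.
#'
#' @param session an `ss_session`.
#' @return character vector, one label per trial.
#' @export
trial_condition <- function(session) {
  tr <- session$trials
  ifelse(tr$kind == "stop",
         ifelse(tr$response == "none", "stop-success", "stop-fail"),
         ifelse(tr$response == "none", "go-omission",
                ifelse(tr$response == tr$direction, "go-success",
                       "go-error")))
}

# draw from Normal(loc, scale) truncated to (lo, hi) by inverse CDF
rtruncnorm1 <- function(n, loc, scale, lo, hi) {
  plo <- pnorm(lo, loc, scale)
  phi <- pnorm(hi, loc, scale)
  qnorm(runif(n, plo, phi), loc, scale)
}

#' Group-level generating distributions for a simulated cohort
#'
#' Describes how subject-level race parameters are drawn within a group:
#' truncated-Normal around group locations (`loc`, a [race_params()]) with
#' group scales (`scale`), the trigger-failure probability handled on the
#' probit scale. Supports are (0, 2000) ms for the mu's and (1, 500) ms for
#' the sigma's and tau's.
#'
#' @param n number of subjects.
#' @param loc group-level locations as a [race_params()]; its `p_tf` is the
#'   group-typical trigger-failure probability.
#' @param scale named numeric vector of group scales for `mu_go`, `sigma_go`,
#'   `tau_go`, `mu_stop`, `sigma_stop`, `tau_stop` and `ptf_probit` (the
#'   scale of the probit-transformed trigger-failure probability).
#' @return a `group_spec` list.
#' @export
group_spec <- function(n, loc, scale) {
  stopifnot(n >= 1, inherits(loc, "race_params"))
  need <- c("mu_go", "sigma_go", "tau_go", "mu_stop", "sigma_stop",
            "tau_stop", "ptf_probit")
  if (!all(need %in% names(scale)))
    stop("scale must name: ", paste(need, collapse = ", "), call. = FALSE)
  structure(list(n = as.integer(n), loc = loc, scale = scale[need]),
            class = "group_spec")
}

#' Default cohort structure
#'
#' The default two-group cohort this package studies: 19 children and 26
#' adults. Children's SSRT distributions are wider and more skewed than
#' adults' (larger sigma_stop and tau_stop, with effect sizes patterned on
#' the large width and moderate tail differences this literature reports),
#' children's go responses are slower, and the groups' mean SSRTs
#' (mu_stop + tau_stop: 264 vs 260 ms) are matched to within a few ms, far
#' inside the 60-ms between-subject spread of mu_stop, so average stopping
#' speed is statistically indistinguishable at these sample sizes while the
#' width and tail parameters separate clearly. The default cohort
#' simulates fully attentive stop-signal triggering (`p_tf = 0`), keeping
#' scaled-down estimation exactly matched to the generator; nonzero
#' trigger-failure rates are available through each group's [race_params()].
#'
#' @return named list of [group_spec()]s (`child`, `adult`).
#' @export
default_group_specs <- function() {
  scl <- c(mu_go = 40, sigma_go = 10, tau_go = 20,
           mu_stop = 60, sigma_stop = 6, tau_stop = 12, ptf_probit = 0.25)
  list(
    child = group_spec(19,
      race_params(mu_go = 450, sigma_go = 60, tau_go = 120,
                  mu_stop = 218, sigma_stop = 48, tau_stop = 46,
                  p_tf = 0), scl),
    adult = group_spec(26,
      race_params(mu_go = 400, sigma_go = 50, tau_go = 100,
                  mu_stop = 226, sigma_stop = 24, tau_stop = 34,
                  p_tf = 0), scl))
}

#' Simulate a multi-group cohort of stop-signal sessions
#'
#' Draws each subject's true race parameters from its group's generating
#' distribution and simulates a full session per subject.
#'
#' @param group_specs named list of [group_spec()]s (default:
#'   [default_group_specs()]).
#' @param design a [task_design()].
#' @param seed integer seed; per-subject seeds are derived deterministically.
#' @param go_error_rate passed to [simulate_session()].
#' @param center_groups if `TRUE`, re-center each group's drawn parameter
#'   values so the realized group means equal the specified group locations
#'   exactly (matched-truth design). With finite groups the sampled means
#'   otherwise wander by up to a few SEM, confounding between-group
#'   contrasts that the study design intends to fix; centering gives exact
#'   control of the realized contrast, as is standard in simulation studies.
#' @return an `ss_cohort`: list with `sessions` (list of `ss_session`) and
#'   `truth` (data frame of each subject's generating parameters).
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' table(coh$truth$group)
#' @export
simulate_cohort <- function(group_specs = default_group_specs(),
                            design = task_design(), seed = NULL,
                            go_error_rate = 0.02, center_groups = FALSE) {
  if (length(group_specs) == 0 || is.null(names(group_specs)))
    stop("group_specs must be a non-empty named list", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # draw every subject's true parameters first, from one uninterrupted
  # stream, then simulate the sessions under well-spaced derived seeds
  # (session RNG must not perturb or alias the parameter draws)
  truth <- list()
  params <- list()
  for (g in names(group_specs)) {
    gs <- group_specs[[g]]
    stopifnot(inherits(gs, "group_spec"))
    loc <- gs$loc; scl <- gs$scale
    for (k in seq_len(gs$n)) {
      p <- race_params(
        mu_go = rtruncnorm1(1, loc$mu_go, scl["mu_go"], 0, 2000),
        sigma_go = rtruncnorm1(1, loc$sigma_go, scl["sigma_go"], 1, 500),
        tau_go = rtruncnorm1(1, loc$tau_go, scl["tau_go"], 1, 500),
        mu_stop = rtruncnorm1(1, loc$mu_stop, scl["mu_stop"], 0, 2000),
        sigma_stop = rtruncnorm1(1, loc$sigma_stop, scl["sigma_stop"], 1, 500),
        tau_stop = rtruncnorm1(1, loc$tau_stop, scl["tau_stop"], 1, 500),
        p_tf = if (loc$p_tf <= 0) 0 else
          pnorm(rtruncnorm1(1, qnorm(loc$p_tf), scl["ptf_probit"], -6, 2)))
      id <- sprintf("%s%02d", substr(g, 1, 1), k)
      params[[id]] <- p
      truth[[id]] <- data.frame(subject_id = id, group = g,
                                mu_go = p$mu_go, sigma_go = p$sigma_go,
                                tau_go = p$tau_go, mu_stop = p$mu_stop,
                                sigma_stop = p$sigma_stop,
                                tau_stop = p$tau_stop, p_tf = p$p_tf,
                                stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (center_groups) {
    parcols <- c("mu_go", "sigma_go", "tau_go",
                 "mu_stop", "sigma_stop", "tau_stop")
    lower <- c(0, 1, 1, 0, 1, 1) + 1e-3
    for (g in names(group_specs)) {
      sel <- truth$group == g
      locs <- unlist(group_specs[[g]]$loc[parcols])
      for (j in seq_along(parcols)) {
        v <- truth[[parcols[j]]][sel]
        truth[[parcols[j]]][sel] <- pmax(v - mean(v) + locs[j], lower[j])
      }
    }
    for (i in seq_len(nrow(truth)))
      params[[truth$subject_id[i]]] <- race_params(
        truth$mu_go[i], truth$sigma_go[i], truth$tau_go[i],
        truth$mu_stop[i], truth$sigma_stop[i], truth$tau_stop[i],
        truth$p_tf[i])
  }
  sessions <- list()
  for (i in seq_along(params)) {
    id <- names(params)[i]
    sess_seed <- if (is.null(seed)) NULL else
      as.integer((abs(as.numeric(seed)) * 100003 + i * 7919) %%
                   2147483647)
    sessions[[id]] <- simulate_session(params[[i]], design,
                                       group = truth$group[i],
                                       subject_id = id, seed = sess_seed,
                                       go_error_rate = go_error_rate)
  }
  structure(list(sessions = sessions, truth = truth, design = design,
                 group_specs = group_specs),
            class = "ss_cohort")
}

#' @export
print.ss_cohort <- function(x, ...) {
  cat(sprintf("Stop-signal cohort: %d sessions (%s)\n", length(x$sessions),
              paste(sprintf("%s n=%d", names(table(x$truth$group)),
                            table(x$truth$group)), collapse = ", ")))
  invisible(x)
}
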