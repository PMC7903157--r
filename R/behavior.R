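#' Quality-control filter on stopping performance
#'
#' A session is excluded when its percentage of successful stop trials falls
#' below `min_stop_success_pct` (default 30%), the conventional cut-off for
#' participants who stop too rarely for race-model estimation.
#'
#' @param session an `ss_session`.
#' @param min_stop_success_pct exclusion threshold in percent.
#' @return logical: `TRUE` if retained, `FALSE` if excluded; the observed
#'   percentage is attached as attribute `"pct_stop_success"`.
#' @export
qc_filter <- function(session, min_stop_success_pct = 30) {
  tr <- session$trials
  st <- tr$kind == "stop"
  if (!any(st))
    stop("session has no stop trials: stop-success rate undefined",
         call. = FALSE)
  pct <- 100 * mean(tr$response[st] == "none")
  structure(pct >= min_stop_success_pct, pct_stop_success = pct)
}

#' Canonical behavioral summary of a stop-signal session
#'
#' Counts, mean SSD over all stop trials, mean RT over correct go trials,
#' percentage of successful stops, and (if computable) the integration-method
#' SSRT.
#'
#' @param session an `ss_session`.
#' @param ssrt if `TRUE`, also compute [compute_ssrt_integration()]
#'   (returns `NA` when undefined).
#' @param ... passed to [compute_ssrt_integration()].
#' @return a one-row data frame of class `stopping_summary`.
#' @examples
#' s <- simulate_session(race_params(400, 50, 100, 200, 30, 50),
#'                       task_design(), seed = 1)
#' summarize_stopping(s)
#' @export
summarize_stopping <- function(session, ssrt = TRUE, ...) {
  tr <- session$trials
  st <- tr$kind == "stop"
  cond <- trial_condition(session)
  go_rt <- tr$rt[cond == "go-success"]
  out <- data.frame(
    subject_id = session$subject_id,
    group = session$group,
    n_go = sum(!st),
    n_stop = sum(st),
    pct_stop_success = if (any(st)) 100 * mean(tr$response[st] == "none")
                       else NA_real_,
    mean_ssd = if (any(st)) mean(tr$ssd[st]) else NA_real_,
    mean_go_rt = if (length(go_rt)) mean(go_rt) else NA_real_,
    stringsAsFactors = FALSE)
  if (ssrt) {
    out$ssrt_integration <- tryCatch(compute_ssrt_integration(session, ...),
                                     error = function(e) NA_real_)
  }
  class(out) <- c("stopping_summary", class(out))
  out
}

#' Integration-method (horse-race) SSRT
#'
#' Implements the canonical integration estimator: rank-order the correct
#' go-trial RTs ascending, find the RT at the quantile given by the observed
#' proportion of failed inhibitions `p` (index `ceiling(p * N)`, no
#' interpolation), and subtract the mean SSD over all stop trials.
#'
#' Go omissions are assigned an RT equal to the response deadline before
#' rank-ordering (limiting the omission bias of the estimator); wrong-
#' direction go responses are excluded from the pool and do not receive the
#' deadline RT.
#'
#' @param session an `ss_session`.
#' @param omission_rt_max if `TRUE` (default) go omissions enter the pool at
#'   `max_rt`; if `FALSE` they are dropped.
#' @return SSRT in ms.
#' @examples
#' s <- simulate_session(race_params(400, 50, 100, 200, 30, 50),
#'                       task_design(), seed = 2)
#' compute_ssrt_integration(s)
#' @export
compute_ssrt_integration <- function(session, omission_rt_max = TRUE) {
  tr <- session$trials
  cond <- trial_condition(session)
  st <- tr$kind == "stop"
  if (!any(st)) stop("no stop trials: SSRT undefined", call. = FALSE)
  p_fail <- mean(tr$response[st] != "none")
  if (p_fail == 0)
    stop("no failed stop trials: the failed-inhibition percentile is ",
         "undefined", call. = FALSE)
  go_rts <- tr$rt[cond == "go-success"]
  if (omission_rt_max)
    go_rts <- c(go_rts, rep(session$design$max_rt, sum(cond == "go-omission")))
  if (length(go_rts) == 0) stop("no usable go RTs", call. = FALSE)
  go_rts <- sort(go_rts)
  idx <- min(length(go_rts), max(1L, ceiling(p_fail * length(go_rts))))
  go_rts[idx] - mean(tr$ssd[st])
}
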