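#' Canonical HRF basis (double-gamma with derivatives)
#'
#' Builds the canonical double-gamma hemodynamic response function sampled on
#' a microtime grid of `tr / microtime` seconds, together with its temporal
#' derivative (finite difference on the grid) and dispersion derivative
#' (finite difference in the peak-dispersion parameter). The canonical
#' kernel is peak-normalized to 1.
#'
#' Defaults follow the common canonical convention: response peak at 6 s,
#' undershoot at 16 s, unit dispersions, undershoot ratio 1/6, 32-s support.
#'
#' @param tr repetition time (s).
#' @param microtime microtime bins per TR.
#' @param peak_delay,under_delay gamma delays (s).
#' @param peak_disp,under_disp gamma dispersions (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length_s kernel support (s).
#' @return an `hrf_basis` list: `time`, `hrf`, `tderiv`, `dderiv`, `dt`.
#' @examples
#' b <- hrf_basis(2.2)
#' b$time[which.max(b$hrf)]   # peak near 5 s
#' @export
hrf_basis <- function(tr, microtime = 16, peak_delay = 6, under_delay = 16,
                      peak_disp = 1, under_disp = 1, ratio = 6,
                      length_s = 32) {
  if (tr <= 0) stop("tr must be > 0", call. = FALSE)
  if (peak_delay <= 0 || under_delay <= 0 || peak_disp <= 0 ||
      under_disp <= 0 || ratio <= 0)
    stop("HRF shape parameters must be positive", call. = FALSE)
  dt <- tr / microtime
  tt <- seq(0, length_s, by = dt)
  dg <- function(disp) {
    dgamma(tt, shape = peak_delay / disp, scale = disp) -
      dgamma(tt, shape = under_delay / under_disp, scale = under_disp) / ratio
  }
  h <- dg(peak_disp)
  h <- h / max(h)
  td <- c(0, diff(h)) / dt
  eps <- 0.01
  dd <- (dg(peak_disp + eps) / max(dg(peak_disp)) - h) / eps
  structure(list(time = tt, hrf = h, tderiv = td, dderiv = dd, dt = dt,
                 microtime = microtime, tr = tr),
            class = "hrf_basis")
}

# convolve per-event sticks (onset s, amplitude, duration s) with a kernel on
# the microtime grid and sample at volume acquisition times. Impulse events
# (zero duration) take a direct kernel-placement path; boxcars go through an
# FFT convolution.
convolve_events <- function(onsets, amplitudes, durations, kernel, dt,
                            n_volumes, tr) {
  n_micro <- ceiling(n_volumes * tr / dt) + length(kernel)
  if (all(durations == 0)) {
    x <- numeric(n_micro)
    nk <- length(kernel)
    for (i in seq_along(onsets)) {
      j0 <- floor(onsets[i] / dt) + 1
      if (j0 > n_micro) next
      j1 <- min(j0 + nk - 1, n_micro)
      x[j0:j1] <- x[j0:j1] + amplitudes[i] * kernel[seq_len(j1 - j0 + 1)]
    }
  } else {
    u <- numeric(n_micro)
    for (i in seq_along(onsets)) {
      j0 <- floor(onsets[i] / dt) + 1
      j1 <- max(j0, j0 + round(durations[i] / dt) - 1)
      if (j0 <= n_micro) u[j0:min(j1, n_micro)] <-
          u[j0:min(j1, n_micro)] + amplitudes[i]
    }
    x <- stats::convolve(u, rev(kernel), type = "open")[seq_len(n_micro)]
  }
  idx <- pmin(n_micro, floor((seq_len(n_volumes) - 1) * tr / dt) + 1)
  x[idx]
}

# discrete-cosine high-pass set (drift terms below 1/cutoff Hz), no constant
dct_highpass <- function(n_volumes, tr, cutoff = 128) {
  if (is.null(cutoff) || !is.finite(cutoff) || cutoff <= 0) return(NULL)
  K <- floor(2 * n_volumes * tr / cutoff)
  if (K < 1) return(NULL)
  t <- seq_len(n_volumes) - 0.5
  X <- vapply(seq_len(K), function(k)
    sqrt(2 / n_volumes) * cos(pi * k * t / n_volumes), numeric(n_volumes))
  colnames(X) <- paste0("dct", seq_len(K))
  X
}

#' Build a GLM design matrix for an event-related run
#'
#' In `standard` mode every condition contributes a canonical regressor plus
#' (optionally) temporal- and dispersion-derivative regressors, error trials
#' are pooled into a single canonical regressor, and nuisance series,
#' discrete-cosine drift terms and an intercept are appended. In
#' `trialwise` mode the design is identical except that the canonical
#' regressor of `condition_of_interest` is replaced by one canonical
#' regressor per trial of that condition; the condition-level derivative
#' regressors are retained so the standard design's column space is nested
#' in the trial-wise one.
#'
#' @param events data frame with `onset` (s), `duration` (s), `trial_type`.
#' @param n_volumes,tr volumes in the run and repetition time (s).
#' @param mode `"standard"` or `"trialwise"`.
#' @param condition_of_interest condition split into per-trial regressors in
#'   trial-wise mode (default `"stop-success"`).
#' @param conditions trial types modelled as conditions (default: all
#'   non-error types present).
#' @param error_types trial types pooled into the error regressor.
#' @param nuisance optional numeric matrix of nuisance series (rows =
#'   volumes).
#' @param hrf an [hrf_basis()] (default built from `tr`).
#' @param derivatives include temporal/dispersion derivatives.
#' @param hp_cutoff high-pass cutoff in s (`NULL` to disable).
#' @return a `design_matrix`: list with `X` (volumes x regressors), `mode`,
#'   `interest_cols` (columns carrying the condition of interest's canonical
#'   response), `rank_deficient` flag.
#' @export
build_design <- function(events, n_volumes, tr,
                         mode = c("standard", "trialwise"),
                         condition_of_interest = "stop-success",
                         conditions = NULL,
                         error_types = c("stop-fail", "go-error",
                                         "go-omission"),
                         nuisance = NULL, hrf = hrf_basis(tr),
                         derivatives = TRUE, hp_cutoff = 128) {
  mode <- match.arg(mode)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  run_len <- n_volumes * tr
  if (any(events$onset < 0) || any(events$onset > run_len))
    stop("event onsets fall outside the run", call. = FALSE)
  if (is.null(conditions))
    conditions <- setdiff(unique(events$trial_type), error_types)
  if (mode == "trialwise" && !(condition_of_interest %in% conditions))
    stop("condition_of_interest is not among the modelled conditions",
         call. = FALSE)

  cols <- list()
  interest <- character(0)
  kernels <- list(canonical = hrf$hrf)
  if (derivatives) kernels <- c(kernels, list(tderiv = hrf$tderiv,
                                              dderiv = hrf$dderiv))
  for (cc in conditions) {
    ev <- events[events$trial_type == cc, , drop = FALSE]
    if (nrow(ev) == 0) next
    if (mode == "trialwise" && cc == condition_of_interest) {
      for (i in seq_len(nrow(ev))) {
        nm <- sprintf("%s_trial%03d", cc, i)
        cols[[nm]] <- convolve_events(ev$onset[i], 1, ev$duration[i],
                                      hrf$hrf, hrf$dt, n_volumes, tr)
        interest <- c(interest, nm)
      }
      for (kn in setdiff(names(kernels), "canonical")) {
        cols[[paste0(cc, "_", kn)]] <-
          convolve_events(ev$onset, rep(1, nrow(ev)), ev$duration,
                          kernels[[kn]], hrf$dt, n_volumes, tr)
      }
    } else {
      for (kn in names(kernels)) {
        nm <- if (kn == "canonical") cc else paste0(cc, "_", kn)
        cols[[nm]] <- convolve_events(ev$onset, rep(1, nrow(ev)),
                                      ev$duration, kernels[[kn]], hrf$dt,
                                      n_volumes, tr)
        if (kn == "canonical" && cc == condition_of_interest)
          interest <- c(interest, nm)
      }
    }
  }
  ev_err <- events[events$trial_type %in% error_types, , drop = FALSE]
  if (nrow(ev_err) > 0)
    cols[["errors"]] <- convolve_events(ev_err$onset, rep(1, nrow(ev_err)),
                                        ev_err$duration, hrf$hrf, hrf$dt,
                                        n_volumes, tr)
  X <- do.call(cbind, cols)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes)
      stop("nuisance rows must equal n_volumes", call. = FALSE)
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  dct <- dct_highpass(n_volumes, tr, hp_cutoff)
  if (!is.null(dct)) X <- cbind(X, dct)
  X <- cbind(X, intercept = 1)
  qr_rank <- qr(X)$rank
  structure(list(X = X, mode = mode,
                 condition_of_interest = condition_of_interest,
                 interest_cols = interest,
                 n_task_cols = length(cols),
                 rank_deficient = qr_rank < ncol(X), rank = qr_rank),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("GLM design (%s mode): %d volumes x %d regressors%s\n",
              x$mode, nrow(x$X), ncol(x$X),
              if (x$rank_deficient)
                sprintf(" [rank deficient: rank %d]", x$rank) else ""))
  invisible(x)
}
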