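#' Labeled synthetic voxel grid
#'
#' The synthetic "brain" is a small labeled grid (default 10 x 10 x 10) with
#' six disjoint 3 x 3 x 3 regions named for the right-lateralized inhibition
#' network (inferior frontal gyrus pars triangularis, caudate, putamen,
#' thalamus, subthalamic nucleus) plus a right calcarine control region.
#' There is no anatomical realism: labels exist so that region-level signal
#' structure and ROI extraction can be exercised with known ground truth.
#'
#' @param dims grid dimensions (each >= 10 to hold the default regions).
#' @return integer vector of length `prod(dims)` with 0 = background and
#'   levels named in attribute `"regions"`; attribute `"dims"` holds the
#'   grid size.
#' @export
synthetic_brain_labels <- function(dims = c(10, 10, 10)) {
  if (any(dims < 10)) stop("dims must be at least 10 in each axis",
                           call. = FALSE)
  regions <- list(
    rIFG       = list(x = 1:3,  y = 1:3,  z = 6:8),
    rCaudate   = list(x = 5:7,  y = 2:4,  z = 4:6),
    rPutamen   = list(x = 8:10, y = 1:3,  z = 1:3),
    rThalamus  = list(x = 5:7,  y = 6:8,  z = 4:6),
    rSTN       = list(x = 8:10, y = 6:8,  z = 1:3),
    rCalcarine = list(x = 1:3,  y = 8:10, z = 7:9))
  lab <- array(0L, dims)
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    lab[r$x, r$y, r$z] <- i
  }
  out <- as.integer(lab)
  attr(out, "regions") <- names(regions)
  attr(out, "dims") <- dims
  out
}

.inhibition_network <- c("rIFG", "rCaudate", "rPutamen", "rThalamus", "rSTN")

#' Default trial-amplitude table for the synthetic BOLD generator
#'
#' One row per (region, condition): the mean and trial-to-trial standard
#' deviation of the single-trial response amplitude, in units of the noise
#' SD. Inhibition-network regions respond to successful stops (the condition
#' whose variability is under study) and weakly to go trials; the calcarine
#' control responds to every visual event with group-independent
#' variability.
#'
#' @param stop_sd trial-amplitude SD of the stop-success response in the
#'   inhibition-network regions.
#' @param calcarine_sd trial-amplitude SD in the control region.
#' @param go_sd trial-amplitude SD of the weak go response in the network.
#' @param err_sd trial-amplitude SD of the error-trial responses. Error
#'   conditions (failed stops, wrong-direction responses, omissions) share
#'   one mean per region, mirroring their pooling into a single GLM
#'   regressor.
#' @return data frame with `region`, `condition`, `mean`, `sd`.
#' @export
default_amp_table <- function(stop_sd = 1.5, calcarine_sd = 0.8,
                              go_sd = 0.2, err_sd = 0.3) {
  err <- c("stop-fail", "go-error", "go-omission")
  rows <- list()
  for (r in .inhibition_network) {
    rows[[length(rows) + 1]] <- data.frame(
      region = r, condition = c("stop-success", "go-success", err),
      mean = c(3, 1, rep(2, 3)), sd = c(stop_sd, go_sd, rep(err_sd, 3)),
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(
    region = "rCalcarine",
    condition = c("stop-success", "go-success", err),
    mean = rep(3, 5), sd = c(calcarine_sd, calcarine_sd, rep(err_sd, 3)),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Specification of a synthetic event-related BOLD run
#'
#' @param dims voxel-grid dimensions.
#' @param tr repetition time (s).
#' @param baseline baseline signal level.
#' @param amp amplitude table as from [default_amp_table()].
#' @param noise_sd stationary SD of the AR(1) noise (>= 0).
#' @param ar1 AR(1) coefficient (|ar1| < 1).
#' @param drift_amp amplitude scale of the linear + sinusoidal drift.
#' @param motion_sd length-2: per-frame random-walk SDs of translations (mm)
#'   and rotations (rad).
#' @return a `bold_sim_spec` list.
#' @export
bold_sim_spec <- function(dims = c(10, 10, 10), tr = 2.2, baseline = 100,
                          amp = default_amp_table(), noise_sd = 1,
                          ar1 = 0.3, drift_amp = 1,
                          motion_sd = c(0.055, 4.8e-4)) {
  if (tr <= 0) stop("tr must be > 0", call. = FALSE)
  if (noise_sd < 0 || any(amp$sd < 0) || drift_amp < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (abs(ar1) >= 1) stop("|ar1| must be < 1", call. = FALSE)
  structure(list(dims = dims, tr = tr, baseline = baseline, amp = amp,
                 noise_sd = noise_sd, ar1 = ar1, drift_amp = drift_amp,
                 motion_sd = motion_sd),
            class = "bold_sim_spec")
}

#' Simulate an event-related BOLD run with known trial amplitudes
#'
#' Each voxel's signal is baseline + the sum over trials of a per-trial
#' amplitude times the canonical HRF shifted to the trial onset, plus AR(1)
#' noise and a slow linear + sinusoidal drift. The amplitude of trial `i` in
#' region `r` is drawn once per (trial, region) from
#' `Normal(mean, sd)` of that region/condition row of the spec's amplitude
#' table and shared by the region's voxels, so the configured `sd` is the
#' ground-truth trial-by-trial variability the difference-of-residuals
#' analysis estimates. A six-parameter random-walk motion trace is emitted
#' alongside.
#'
#' @param events data frame with `onset` (s), `duration` (s), `trial_type`.
#' @param spec a [bold_sim_spec()].
#' @param run_duration run length in s (default: last onset + 24 s);
#'   the number of volumes is `floor(run_duration / tr)`.
#' @param seed optional integer seed.
#' @return a `bold_run`: list with `data` (voxels x volumes matrix),
#'   `dims`, `labels`, `tr`, `n_volumes`, `events`, `motion` (volumes x 6)
#'   and `truth` (long data frame of generated per-trial region amplitudes).
#' @export
simulate_bold_run <- function(events, spec = bold_sim_spec(),
                              run_duration = NULL, seed = NULL) {
  stopifnot(inherits(spec, "bold_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(run_duration)) run_duration <- max(events$onset) + 24
  if (any(events$onset > run_duration))
    stop("run_duration does not cover all events", call. = FALSE)
  n_vol <- floor(run_duration / spec$tr + 1e-9)
  labels <- synthetic_brain_labels(spec$dims)
  regions <- attr(labels, "regions")
  n_vox <- prod(spec$dims)
  hb <- hrf_basis(spec$tr)

  Y <- matrix(spec$baseline, n_vox, n_vol)

  # region-level trial responses with known amplitudes
  truth <- list()
  for (ri in seq_along(regions)) {
    rows <- spec$amp[spec$amp$region == regions[ri], , drop = FALSE]
    if (nrow(rows) == 0) next
    sel <- match(events$trial_type, rows$condition)
    hit <- which(!is.na(sel))
    if (length(hit) == 0) next
    amps <- rnorm(length(hit), rows$mean[sel[hit]], rows$sd[sel[hit]])
    sig <- convolve_events(events$onset[hit], amps, events$duration[hit],
                           hb$hrf, hb$dt, n_vol, spec$tr)
    vox <- which(labels == ri)
    Y[vox, ] <- Y[vox, ] + rep(sig, each = length(vox))
    truth[[regions[ri]]] <- data.frame(
      event = hit, trial_type = events$trial_type[hit],
      region = regions[ri], amplitude = amps, stringsAsFactors = FALSE)
  }

  # AR(1) noise with stationary SD noise_sd, vectorized over voxels
  if (spec$noise_sd > 0) {
    innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
    eps <- matrix(rnorm(n_vox * n_vol, 0, innov_sd), n_vox, n_vol)
    eps[, 1] <- rnorm(n_vox, 0, spec$noise_sd)
    for (t in 2:n_vol) eps[, t] <- spec$ar1 * eps[, t - 1] + eps[, t]
    Y <- Y + eps
  }

  if (spec$drift_amp > 0) {
    tt <- seq_len(n_vol) / n_vol
    slope <- runif(n_vox, -1, 1) * spec$drift_amp
    samp <- runif(n_vox, 0, spec$drift_amp)
    phase <- runif(n_vox, 0, 2 * pi)
    Y <- Y + outer(slope, tt - 0.5) +
      samp * sin(outer(rep(2 * pi, n_vox), tt) + phase)
  }

  motion <- cbind(
    vapply(1:3, function(i) cumsum(rnorm(n_vol, 0, spec$motion_sd[1])),
           numeric(n_vol)),
    vapply(1:3, function(i) cumsum(rnorm(n_vol, 0, spec$motion_sd[2])),
           numeric(n_vol)))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(event = integer(0), trial_type = character(0),
               region = character(0), amplitude = numeric(0))
  rownames(truth) <- NULL
  structure(list(data = Y, dims = spec$dims, labels = labels, tr = spec$tr,
                 n_volumes = n_vol, events = events, motion = motion,
                 truth = truth),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("Synthetic BOLD run: %d voxels (%s grid) x %d volumes, TR %g s\n",
              nrow(x$data), paste(x$dims, collapse = "x"), x$n_volumes,
              x$tr))
  cat(sprintf("  %d events (%s)\n", nrow(x$events),
              paste(names(table(x$events$trial_type)), collapse = ", ")))
  invisible(x)
}

#' Voxel-wise residual sum of squares of a GLM
#'
#' Ordinary least squares of every voxel's time series on the design matrix.
#' Returns the raw residual sum of squares per voxel, deliberately not
#' divided by the residual degrees of freedom: the trial-wise model's df
#' depends on the (subject-varying) number of trials of the condition of
#' interest, and dividing would bias the difference of residuals across
#' subjects.
#'
#' @param bold a `bold_run` or a voxels x volumes matrix.
#' @param design a [build_design()] result (rows must equal volumes).
#' @return an `ssr_map`: list with `ssr` (vector, one value per voxel),
#'   `mode`, `condition_of_interest`, `dims`.
#' @export
fit_glm_ssr <- function(bold, design) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- if (inherits(bold, "bold_run")) bold$data else as.matrix(bold)
  dims <- if (inherits(bold, "bold_run")) bold$dims else NULL
  if (ncol(Y) != nrow(design$X))
    stop("design rows (", nrow(design$X), ") must equal run volumes (",
         ncol(Y), ")", call. = FALSE)
  qrX <- qr(design$X)
  res <- qr.resid(qrX, t(Y))
  structure(list(ssr = colSums(res^2), mode = design$mode,
                 condition_of_interest = design$condition_of_interest,
                 dims = dims, n_volumes = nrow(design$X),
                 rank = qrX$rank),
            class = "ssr_map")
}

#' Difference of residuals (DoR): trial-by-trial BOLD variability
#'
#' The voxel-wise residual sum of squares of the condition-averaged
#' (standard) GLM minus that of the trial-wise GLM. Because the trial-wise
#' design's column space contains the standard design's, the difference is
#' nonnegative and captures exactly the signal variance absorbed by the
#' per-trial regressors of the condition of interest — an estimate of that
#' condition's trial-by-trial response variability. Values within
#' `-tolerance` of zero (numerical noise) are clipped to 0.
#'
#' @param ssr_standard,ssr_trialwise `ssr_map`s from the same run in
#'   standard and trialwise mode.
#' @param tolerance numerical tolerance for the nonnegativity clip.
#' @return a `dor_map`: list with `dor` (vector per voxel), `dims`,
#'   `condition_of_interest`.
#' @export
difference_of_residuals <- function(ssr_standard, ssr_trialwise,
                                    tolerance = 1e-6) {
  stopifnot(inherits(ssr_standard, "ssr_map"),
            inherits(ssr_trialwise, "ssr_map"))
  if (ssr_standard$mode != "standard" || ssr_trialwise$mode != "trialwise")
    stop("pass the standard-mode map first and the trialwise-mode map ",
         "second", call. = FALSE)
  if (length(ssr_standard$ssr) != length(ssr_trialwise$ssr) ||
      ssr_standard$n_volumes != ssr_trialwise$n_volumes)
    stop("residual maps come from different runs/grids", call. = FALSE)
  dor <- ssr_standard$ssr - ssr_trialwise$ssr
  scale_tol <- tolerance * pmax(ssr_standard$ssr, 1)
  if (any(dor < -scale_tol))
    warning("negative DoR beyond tolerance at ",
            sum(dor < -scale_tol), " voxel(s); check design nesting")
  dor[dor < 0] <- 0
  structure(list(dor = dor, dims = ssr_standard$dims,
                 condition_of_interest = ssr_standard$condition_of_interest),
            class = "dor_map")
}

#' Confound regression (denoising)
#'
#' Regresses every voxel's time series on an intercept, the supplied
#' confound series (e.g. white-matter and CSF means plus realignment
#' parameters) and one indicator column per flagged outlier volume, and
#' returns the residuals (voxel means removed).
#'
#' @param bold a `bold_run` or voxels x volumes matrix.
#' @param confounds numeric matrix (volumes x series), or `NULL`.
#' @param outliers integer indices of volumes to scrub via indicator
#'   regressors.
#' @return the input with `data` replaced by the denoised residuals.
#' @export
denoise <- function(bold, confounds = NULL, outliers = integer(0)) {
  Y <- if (inherits(bold, "bold_run")) bold$data else as.matrix(bold)
  n_vol <- ncol(Y)
  if (length(outliers) >= n_vol)
    stop("all volumes flagged as outliers", call. = FALSE)
  X <- matrix(1, n_vol, 1)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n_vol)
      stop("confound rows must equal volumes", call. = FALSE)
    X <- cbind(X, confounds)
  }
  for (o in outliers) {
    ind <- numeric(n_vol); ind[o] <- 1
    X <- cbind(X, ind)
  }
  res <- t(qr.resid(qr(X), t(Y)))
  if (inherits(bold, "bold_run")) {
    bold$data <- res
    bold
  } else res
}

#' Mean framewise displacement
#'
#' Head-motion summary: for each frame transition, the sum of absolute
#' backward differences of the six realignment parameters, with rotations
#' converted to arc length on a sphere (default radius 50 mm); averaged over
#' the `N - 1` transitions.
#'
#' @param motion volumes x 6 matrix: 3 translations (mm), then 3 rotations
#'   (rad).
#' @param radius rotation-to-displacement conversion radius (mm).
#' @return mean framewise displacement (mm).
#' @export
mean_framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop("motion must have 6 columns (3 translations, 3 rotations)",
         call. = FALSE)
  if (nrow(motion) < 2) stop("need at least 2 volumes", call. = FALSE)
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * radius
  mean(rowSums(d))
}
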