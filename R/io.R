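#' Read and write stop-signal sessions as TSV
#'
#' One row per trial with the documented column order `subject_id`, `group`,
#' `index`, `block`, `kind`, `direction`, `ssd`, `response`, `rt`, `onset`.
#' Several sessions may share a file; [read_sessions_tsv()] splits them by
#' subject. Design metadata (needed to reconstruct sessions) is stored in
#' `# key: value` header comments.
#'
#' @param sessions an `ss_session`, a list of them, or an `ss_cohort`.
#' @param path output file.
#' @return `write_sessions_tsv` returns `path` invisibly;
#'   `read_sessions_tsv` a list of `ss_session` objects (without truth).
#' @export
write_sessions_tsv <- function(sessions, path) {
  if (inherits(sessions, "ss_cohort")) sessions <- sessions$sessions
  if (inherits(sessions, "ss_session")) sessions <- list(sessions)
  d <- sessions[[1]]$design
  hdr <- sprintf(
    paste0("# n_blocks: %d\n# trials_per_block: %d\n# stop_fraction: %g\n",
           "# gap_pattern: %s\n# ssd_start: %g\n# ssd_step: %g\n",
           "# max_rt: %g\n# iti_jitter: %g,%g\n"),
    d$n_blocks, d$trials_per_block, d$stop_fraction,
    paste(d$gap_pattern, collapse = ","), d$ssd_start, d$ssd_step,
    d$max_rt, d$iti_jitter[1], d$iti_jitter[2])
  tab <- do.call(rbind, lapply(sessions, function(s)
    cbind(subject_id = s$subject_id, group = s$group, s$trials)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sub("\n$", "", hdr), con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_sessions_tsv
#' @export
read_sessions_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), hdr, value = TRUE))
  num <- function(key) as.numeric(strsplit(getv(key), ",")[[1]])
  design <- task_design(n_blocks = num("n_blocks"),
                        trials_per_block = num("trials_per_block"),
                        stop_fraction = num("stop_fraction"),
                        gap_pattern = num("gap_pattern"),
                        ssd_start = num("ssd_start"),
                        ssd_step = num("ssd_step"),
                        max_rt = num("max_rt"),
                        iti_jitter = num("iti_jitter"))
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  lapply(split(tab, tab$subject_id)[unique(tab$subject_id)], function(df) {
    structure(list(subject_id = df$subject_id[1], group = df$group[1],
                   design = design, truth = NULL,
                   trials = df[, c("index", "block", "kind", "direction",
                                   "ssd", "response", "rt", "onset")]),
              class = "ss_session")
  })
}

#' BIDS-style events table for a session block
#'
#' @param session an `ss_session`.
#' @param block which block (run) to extract.
#' @param duration event duration in s (0 for impulse events).
#' @return data frame with `onset`, `duration`, `trial_type` (the outcome
#'   condition, see [trial_condition()]).
#' @export
session_events <- function(session, block = 1, duration = 0) {
  tr <- session$trials
  cond <- trial_condition(session)
  sel <- tr$block == block
  data.frame(onset = tr$onset[sel], duration = duration,
             trial_type = cond[sel], stringsAsFactors = FALSE)
}

#' @rdname session_events
#' @param events an events data frame.
#' @param path output file.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a voxel map or 4D run as NIfTI-1
#'
#' Voxel vectors (`dor_map`, `ssr_map`) are reshaped to the 3D grid; a
#' `bold_run`'s voxels x time matrix becomes a 4D volume with the TR stored
#' in the time pixdim.
#'
#' @param x a `dor_map`, `ssr_map`, `bold_run`, or numeric array.
#' @param path output `.nii`/`.nii.gz` path.
#' @param dims grid dims (required for bare vectors).
#' @return `write_nifti` returns `path` invisibly; `read_nifti_map` the
#'   image as a numeric array.
#' @export
write_nifti <- function(x, path, dims = NULL) {
  if (inherits(x, "dor_map")) {
    arr <- array(x$dor, x$dims)
  } else if (inherits(x, "ssr_map")) {
    arr <- array(x$ssr, x$dims)
  } else if (inherits(x, "bold_run")) {
    arr <- array(x$data, c(x$dims, x$n_volumes))
    img <- RNifti::asNifti(arr)
    img$pixdim[5] <- x$tr
    RNifti::writeNifti(img, path)
    return(invisible(path))
  } else if (!is.null(dims)) {
    arr <- array(as.numeric(x), dims)
  } else {
    arr <- as.array(x)
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write a motion-parameter series as 6-column TSV
#'
#' @param motion volumes x 6 matrix.
#' @param path output file.
#' @export
write_motion_tsv <- function(motion, path) {
  write.table(motion, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist posterior draws as a long TSV table
#'
#' Columns `chain`, `iteration`, `parameter`, `value` (retained draws only).
#'
#' @param fit a `race_fit`.
#' @param path output file.
#' @export
write_posterior_tsv <- function(fit, path) {
  d <- dim(fit$draws)
  long <- data.frame(
    chain = rep(seq_len(d[2]), each = d[1], times = d[3]),
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(fit$par_names, each = d[1] * d[2]),
    value = as.vector(fit$draws))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
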