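#' Stop-signal task design
#'
#' Describes the structure of a visual stop-signal session: blocks of go and
#' stop trials in pseudo-random order, a staircase-tracked stop-signal delay
#' (SSD), a response deadline and jittered inter-trial intervals.
#'
#' The default reproduces the study design this package emulates: two blocks
#' of 128 trials, 25% stop trials, every stop trial preceded by a run of 1,
#' 2, 4 or 5 go trials, SSD starting at 250 ms and moving up/down in 50-ms
#' steps (up after a successful stop, down after a failed one), responses
#' collected for at most 1500 ms, and a fixation interval jittered uniformly
#' between 2000 and 4000 ms that is extended by `1500 - RT` ms after a
#' response so all sessions last equally long.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials in each block.
#' @param stop_fraction fraction of stop trials per block;
#'   `stop_fraction * trials_per_block` must be a whole number.
#' @param gap_pattern go-run lengths allowed immediately before a stop trial.
#'   Each block uses an equal number of repetitions of each gap, so the gaps
#'   must tile the go-trial count exactly.
#' @param ssd_start,ssd_step initial SSD and staircase step (ms).
#' @param max_rt response deadline (ms).
#' @param iti_jitter length-2 numeric, uniform jitter bounds for the
#'   inter-trial fixation (ms).
#' @return an object of class `task_design`.
#' @examples
#' d <- task_design()
#' d$trials_per_block * d$stop_fraction   # 32 stop trials per block
#' @export
task_design <- function(n_blocks = 2, trials_per_block = 128,
                        stop_fraction = 0.25, gap_pattern = c(1, 2, 4, 5),
                        ssd_start = 250, ssd_step = 50, max_rt = 1500,
                        iti_jitter = c(2000, 4000)) {
  n_stop <- stop_fraction * trials_per_block
  if (abs(n_stop - round(n_stop)) > 1e-9)
    stop("stop_fraction * trials_per_block must be an integer", call. = FALSE)
  n_stop <- as.integer(round(n_stop))
  n_go <- trials_per_block - n_stop
  if (n_stop > 0) {
    reps <- n_go / sum(gap_pattern)
    if (n_stop %% length(gap_pattern) != 0 ||
        abs(reps - round(reps)) > 1e-9 ||
        round(reps) * length(gap_pattern) != n_stop)
      stop("gap_pattern cannot tile the block: need an equal number of ",
           "repetitions of each gap summing to the go-trial count",
           call. = FALSE)
  }
  if (ssd_step <= 0) stop("ssd_step must be > 0", call. = FALSE)
  if (max_rt <= 0) stop("max_rt must be > 0", call. = FALSE)
  if (length(iti_jitter) != 2 || iti_jitter[1] > iti_jitter[2])
    stop("iti_jitter must be (min, max)", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 stop_fraction = stop_fraction,
                 gap_pattern = as.integer(gap_pattern),
                 n_stop_per_block = n_stop, n_go_per_block = n_go,
                 ssd_start = ssd_start, ssd_step = ssd_step,
                 max_rt = max_rt, iti_jitter = iti_jitter),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(
    "Stop-signal task design: %d block(s) x %d trials (%d go + %d stop)\n",
    x$n_blocks, x$trials_per_block, x$n_go_per_block, x$n_stop_per_block))
  cat(sprintf("  gaps before stops: {%s}; SSD start %g ms, step %g ms\n",
              paste(x$gap_pattern, collapse = ","), x$ssd_start, x$ssd_step))
  cat(sprintf("  response deadline %g ms; ITI jitter [%g, %g] ms\n",
              x$max_rt, x$iti_jitter[1], x$iti_jitter[2]))
  invisible(x)
}

#' Generate a pseudo-randomized trial sequence
#'
#' Lays out trial kinds and arrow directions for every block of a design:
#' each block contains exactly `stop_fraction * trials_per_block` stop
#' trials, each preceded by a run of go trials whose length is drawn (without
#' replacement, equal repetitions) from the design's gap pattern, and
#' left/right directions balanced within one trial per block.
#'
#' @param design a [task_design()].
#' @param seed optional integer seed.
#' @return data frame with columns `index`, `block`, `kind` ("go"/"stop"),
#'   `direction` ("left"/"right").
#' @examples
#' trials <- generate_trial_sequence(task_design(), seed = 1)
#' table(trials$block, trials$kind)
#' @export
generate_trial_sequence <- function(design, seed = NULL) {
  stopifnot(inherits(design, "task_design"))
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(seq_len(design$n_blocks), function(b) {
    n_stop <- design$n_stop_per_block
    if (n_stop == 0) {
      kind <- rep("go", design$trials_per_block)
    } else {
      reps <- n_stop / length(design$gap_pattern)
      gaps <- sample(rep(design$gap_pattern, reps))
      kind <- unlist(lapply(gaps, function(g) c(rep("go", g), "stop")),
                     use.names = FALSE)
    }
    n <- length(kind)
    n_left <- floor(n / 2)
    direction <- sample(c(rep("left", n_left), rep("right", n - n_left)))
    data.frame(block = b, kind = kind, direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
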