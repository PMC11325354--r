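# Block-design ROI quantification: percent signal change against the
# pre-onset baseline, the 8-12 s response magnitude, and the motion- and
# performance-based exclusion rules.

BLOCK_TIMES <- seq(-4, 18, by = 2)   # 12 samples, TR = 2 s
FD_WINDOW_TIMES <- -8:6              # TR offsets: 8 before onset .. 2 after
                                     # a 5-TR (10 s) stimulus block

#' A block-design ROI time course
#'
#' Twelve ROI samples at times -4, -2, 0, ..., 18 s relative to stimulus
#' onset (TR = 2 s), with the framewise-displacement trace covering the
#' exclusion window (8 TRs before the stimulus block through 2 TRs after it)
#' and the run's hit rate on the central fixation task.
#'
#' @param samples Numeric vector of 12 raw ROI values.
#' @param fd Framewise displacement per TR (mm, `>= 0`).
#' @param fd_times TR offsets of `fd` relative to stimulus onset; defaults
#'   to the exclusion window `-8:6` (a 5-TR stimulus block).
#' @param subject,run,block,condition Identifiers.
#' @param hit_rate Proportion correct on the fixation task for the run.
#' @param amplitude_true Optional planted amplitude (synthetic data only).
#' @return An object of class `block_timecourse`.
#' @export
block_timecourse <- function(samples, fd, fd_times = FD_WINDOW_TIMES,
                             subject = "", run = 1L, block = 1L,
                             condition = "", hit_rate = 1,
                             amplitude_true = NA_real_) {
  if (length(samples) != 12L || any(!is.finite(samples))) {
    stop("block_timecourse: need exactly 12 finite samples", call. = FALSE)
  }
  if (length(fd) != length(fd_times)) {
    stop("block_timecourse: fd and fd_times lengths differ", call. = FALSE)
  }
  if (any(!is.finite(fd)) || any(fd < 0)) {
    stop("block_timecourse: FD values must be finite and >= 0",
         call. = FALSE)
  }
  if (!is.finite(hit_rate) || hit_rate < 0 || hit_rate > 1) {
    stop("block_timecourse: hit_rate must lie in [0, 1]", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), times = BLOCK_TIMES,
                 fd = as.numeric(fd), fd_times = as.integer(fd_times),
                 subject = subject, run = run, block = block,
                 condition = condition, hit_rate = hit_rate,
                 amplitude_true = amplitude_true),
            class = "block_timecourse")
}

#' @export
print.block_timecourse <- function(x, ...) {
  cat(sprintf(
    "<block_timecourse> %s run %s block %s (%s): max FD %.2f mm, hit rate %.2f\n",
    x$subject, x$run, x$block, x$condition, max(x$fd), x$hit_rate))
  invisible(x)
}

#' Percent signal change of a block
#'
#' Converts the raw samples to percent signal change relative to the mean of
#' the three samples before stimulus onset (t = -4, -2, 0 s):
#' `psc = (raw / baseline - 1) * 100`. The PSC over the baseline samples
#' averages exactly zero by construction.
#'
#' @param block A [block_timecourse()].
#' @return Numeric vector of 12 PSC values.
#' @export
percent_signal_change <- function(block) {
  baseline <- mean(block$samples[1:3])
  if (!is.finite(baseline) || baseline <= 0) {
    stop("percent_signal_change: non-positive baseline; block rejected",
         call. = FALSE)
  }
  (block$samples / baseline - 1) * 100
}

#' Response magnitude of a PSC time course
#'
#' The univariate response measure: the mean PSC over the samples at
#' t = 8, 10 and 12 s (both endpoints included).
#'
#' @param psc A 12-sample PSC vector (from [percent_signal_change()]).
#' @return Scalar mean response.
#' @export
response_magnitude <- function(psc) {
  stopifnot(length(psc) == 12L)
  mean(psc[BLOCK_TIMES %in% c(8, 10, 12)])
}

#' Head-motion exclusion of a block
#'
#' A block is excluded when the framewise displacement exceeds
#' `fd_threshold` (0.9 mm) anywhere in the window from 8 TRs before the
#' stimulus block through 2 TRs after it. FD values supplied outside the
#' window are ignored; an incompletely covered window is an error.
#'
#' @param block A [block_timecourse()].
#' @param fd_threshold Exclusion threshold in mm (default 0.9).
#' @return `TRUE` if the block is excluded.
#' @export
exclude_block <- function(block, fd_threshold = 0.9) {
  in_window <- block$fd_times %in% FD_WINDOW_TIMES
  if (!all(FD_WINDOW_TIMES %in% block$fd_times)) {
    stop("exclude_block: FD trace does not cover the full exclusion window",
         call. = FALSE)
  }
  any(block$fd[in_window] > fd_threshold)
}

#' Run-level exclusion
#'
#' A run is excluded when more than one-half of the blocks of either
#' condition are excluded, or when the run's hit rate on the fixation task
#' is below 60%.
#'
#' @param blocks List of [block_timecourse()] objects belonging to one run.
#' @param hit_rate The run's hit rate; defaults to the value carried by the
#'   blocks.
#' @param fd_threshold Passed to [exclude_block()].
#' @return `TRUE` if the run is excluded.
#' @export
exclude_run <- function(blocks, hit_rate = NULL, fd_threshold = 0.9) {
  if (length(blocks) == 0L) {
    stop("exclude_run: no blocks supplied", call. = FALSE)
  }
  if (is.null(hit_rate)) hit_rate <- blocks[[1]]$hit_rate
  if (hit_rate < 0.6) return(TRUE)
  cond <- vapply(blocks, `[[`, character(1), "condition")
  excl <- vapply(blocks, exclude_block, logical(1),
                 fd_threshold = fd_threshold)
  for (cd in unique(cond)) {
    sel <- cond == cd
    if (sum(excl[sel]) > sum(sel) / 2) return(TRUE)
  }
  FALSE
}

#' Per-subject, per-condition response magnitudes
#'
#' Applies the block- and run-level exclusion rules and averages the
#' response magnitudes of the retained blocks per subject and condition,
#' producing a table ready for correlation with regional surface area.
#'
#' @param blocks List of [block_timecourse()] objects (all subjects/runs).
#' @param fd_threshold Passed to the exclusion rules.
#' @return A data frame with `subject`, `condition`, `response`, `n_blocks`;
#'   conditions with no retained blocks get `NA`.
#' @export
condition_response <- function(blocks, fd_threshold = 0.9) {
  sid <- vapply(blocks, `[[`, character(1), "subject")
  run <- vapply(blocks, function(b) as.integer(b$run), integer(1))
  cond <- vapply(blocks, `[[`, character(1), "condition")
  run_key <- paste(sid, run)
  run_excluded <- vapply(split(blocks, run_key), exclude_run, logical(1),
                         fd_threshold = fd_threshold)
  keep_run <- !run_excluded[run_key]
  block_excl <- vapply(blocks, exclude_block, logical(1),
                       fd_threshold = fd_threshold)
  keep <- keep_run & !block_excl
  mag <- vapply(blocks, function(b)
    response_magnitude(percent_signal_change(b)), numeric(1))
  out <- expand.grid(subject = unique(sid), condition = unique(cond),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$response <- NA_real_
  out$n_blocks <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- keep & sid == out$subject[i] & cond == out$condition[i]
    if (any(sel)) {
      out$response[i] <- mean(mag[sel])
      out$n_blocks[i] <- sum(sel)
    }
  }
  out
}
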