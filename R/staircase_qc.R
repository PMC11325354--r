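# Staircase quality control and per-condition aggregation. The quality rule
# targets "rising staircases": the mean running threshold estimate over the
# final 5 trials divided by the mean over the first 10 trials; a ratio above
# 0.8 marks the staircase as unreliable (a converged staircase ends well
# below its early, prior-dominated estimates).

#' Staircase quality statistic
#'
#' @param record A `staircase_record` from [run_staircase()], or any list
#'   with a `trials` data frame containing an `estimate` column of running
#'   per-trial threshold estimates.
#' @param cutoff Flagging cutoff (default 0.8); staircases are flagged when
#'   the ratio strictly exceeds it.
#' @return A list with `ratio` and `flagged`.
#' @export
#' @examples
#' est <- c(seq(200, 110, length.out = 10), rep(40, 15))
#' staircase_quality(list(trials = data.frame(estimate = est)))
staircase_quality <- function(record, cutoff = 0.8) {
  est <- record$trials$estimate
  if (is.null(est) || length(est) < 15L) {
    stop("staircase_quality: need >= 15 trials with running estimates",
         call. = FALSE)
  }
  first10 <- mean(est[1:10])
  last5 <- mean(est[(length(est) - 4L):length(est)])
  if (first10 == 0) {
    stop("staircase_quality: zero mean over the first 10 estimates",
         call. = FALSE)
  }
  ratio <- last5 / first10
  list(ratio = ratio, flagged = ratio > cutoff)
}

#' Aggregate staircase thresholds for one condition
#'
#' The final threshold estimate for a condition is the median of the
#' surviving (non-flagged) per-staircase 80% thresholds; the study ran four
#' staircases per condition.
#'
#' @param records A list of `staircase_record` objects (or lists with
#'   `threshold_80` and `flagged` fields).
#' @return The median threshold over non-flagged records.
#' @export
aggregate_threshold <- function(records) {
  if (length(records) == 0L) {
    stop("aggregate_threshold: no records supplied", call. = FALSE)
  }
  thr <- vapply(records, function(r) r$threshold_80, numeric(1))
  flg <- vapply(records, function(r) isTRUE(r$flagged), logical(1))
  if (all(flg)) {
    stop("aggregate_threshold: all staircases flagged; no valid estimate ",
         "for condition", call. = FALSE)
  }
  stats::median(thr[!flg])
}

#' Subject-level exclusion rule
#'
#' A subject with 4 or more flagged staircases (across all conditions and
#' runs) is considered for exclusion.
#'
#' @param records A list of `staircase_record` objects for one subject, or a
#'   logical vector of per-staircase flags.
#' @param max_flags Flag count at or above which the subject is excluded
#'   (default 4).
#' @return `TRUE` if the subject meets the exclusion rule.
#' @export
subject_exclusion <- function(records, max_flags = 4) {
  flg <- if (is.logical(records)) {
    records
  } else {
    vapply(records, function(r) isTRUE(r$flagged), logical(1))
  }
  sum(flg) >= max_flags
}
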