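# Bayesian adaptive (Psi) staircase after Kontsevich & Tyler: each trial
# presents the stimulus that minimizes the expected posterior entropy over a
# (alpha, beta) lattice, assuming the same fixed-guess/fixed-lapse Weibull
# family used for the final fit.

#' Initialize a Psi staircase state
#'
#' Defaults follow standard Psi practice for the motion duration task: a
#' 41-point log-spaced stimulus grid over 6.7-333 ms that doubles as the
#' alpha lattice, a 17-point log-spaced beta lattice over 0.5-16, and a
#' uniform prior. Contrast-detection mode uses a log-spaced contrast grid
#' over 0.001-1.
#'
#' @param mode `"duration"` or `"contrast"`.
#' @param stimulus_grid Candidate stimulus values (ascending). Defaults per
#'   mode as above.
#' @param alpha_grid Lattice of alpha values; defaults to `stimulus_grid`.
#' @param beta_grid Lattice of beta values.
#' @param prior Prior mass over the `length(alpha_grid) * length(beta_grid)`
#'   lattice (alpha varying fastest); uniform if `NULL`.
#' @param gamma,lambda Fixed guess and lapse rates of the internal Weibull
#'   family.
#' @return An object of class `psi_state`.
#' @export
psi_init <- function(mode = c("duration", "contrast"),
                     stimulus_grid = NULL, alpha_grid = NULL,
                     beta_grid = NULL, prior = NULL,
                     gamma = 0.5, lambda = 0.04) {
  mode <- match.arg(mode)
  if (is.null(stimulus_grid)) {
    stimulus_grid <- if (mode == "duration") {
      exp(seq(log(6.7), log(333), length.out = 41))
    } else {
      exp(seq(log(0.001), log(1), length.out = 41))
    }
  }
  if (is.unsorted(stimulus_grid, strictly = TRUE) || any(stimulus_grid <= 0)) {
    stop("psi_init: stimulus_grid must be strictly increasing and positive",
         call. = FALSE)
  }
  if (is.null(alpha_grid)) alpha_grid <- stimulus_grid
  if (is.null(beta_grid)) {
    beta_grid <- exp(seq(log(0.5), log(16), length.out = 17))
  }
  n_theta <- length(alpha_grid) * length(beta_grid)
  if (is.null(prior)) prior <- rep(1 / n_theta, n_theta)
  if (length(prior) != n_theta || any(prior < 0) || sum(prior) <= 0) {
    stop("psi_init: prior must be non-negative mass over the ",
         "alpha x beta lattice", call. = FALSE)
  }
  theta <- expand.grid(alpha = alpha_grid, beta = beta_grid,
                       KEEP.OUT.ATTRS = FALSE)
  # likelihood of a correct response at each lattice point x stimulus
  P <- matrix(0, n_theta, length(stimulus_grid))
  for (j in seq_along(stimulus_grid)) {
    P[, j] <- gamma + (1 - gamma - lambda) *
      (1 - exp(-(stimulus_grid[j] / theta$alpha)^theta$beta))
  }
  structure(list(
    mode = mode, stimulus_grid = stimulus_grid, alpha_grid = alpha_grid,
    beta_grid = beta_grid, theta = theta, P = P,
    logP = log(P), log1mP = log1p(-P),
    posterior = prior / sum(prior), gamma = gamma, lambda = lambda,
    history = data.frame(trial = integer(0), stimulus = numeric(0),
                         correct = integer(0), estimate = numeric(0))
  ), class = "psi_state")
}

#' @export
print.psi_state <- function(x, ...) {
  cat(sprintf(
    "<psi_state> %s mode: %d stimuli [%.4g, %.4g], %d x %d lattice, %d trials\n",
    x$mode, length(x$stimulus_grid), min(x$stimulus_grid),
    max(x$stimulus_grid), length(x$alpha_grid), length(x$beta_grid),
    nrow(x$history)))
  if (nrow(x$history) > 0) {
    cat(sprintf("  running alpha estimate: %.4g\n",
                x$history$estimate[nrow(x$history)]))
  }
  invisible(x)
}

xlogx <- function(v) ifelse(v > 0, v * log(v), 0)

# Expected posterior entropy per candidate stimulus, given a posterior mass
# vector and the precomputed likelihood matrix P (theta x stimulus). With
# logP/log1mP supplied, log(M) = log(post) + log(P) is assembled from the
# precomputed parts (posterior mass of zero contributes zero, as in xlogx).
psi_eh <- function(post, P, logP = NULL, log1mP = NULL) {
  M <- post * P             # joint mass of (theta, correct) per stimulus
  Mi <- post - M            # joint mass of (theta, incorrect)
  pc <- colSums(M)
  pi_ <- colSums(Mi)
  if (is.null(logP)) {
    sum_mlogm_c <- colSums(xlogx(M))
    sum_mlogm_i <- colSums(xlogx(Mi))
  } else {
    lp <- ifelse(post > 0, log(post), 0)
    sum_mlogm_c <- colSums(M * lp + M * logP)
    sum_mlogm_i <- colSums(Mi * lp + Mi * log1mP)
  }
  h_c <- ifelse(pc > 0, -sum_mlogm_c / pc + log(pc), 0)
  h_i <- ifelse(pi_ > 0, -sum_mlogm_i / pi_ + log(pi_), 0)
  pc * h_c + pi_ * h_i
}

# Expected posterior entropy for each candidate stimulus (vector over grid).
psi_expected_entropy <- function(state) {
  psi_eh(state$posterior, state$P)
}

#' Select the next Psi stimulus
#'
#' Returns the stimulus-grid value minimizing the expected posterior entropy
#' over the (alpha, beta) lattice after the next trial. Ties (within 1e-12)
#' break toward the smaller stimulus, so a degenerate single-point posterior
#' yields the smallest candidate.
#'
#' @param state A [psi_init()] state.
#' @return The selected stimulus value, with the grid index as attribute
#'   `"index"`.
#' @export
psi_select <- function(state) {
  stopifnot(inherits(state, "psi_state"))
  eh <- psi_expected_entropy(state)
  j <- which(eh <= min(eh) + 1e-12)[1L]
  structure(state$stimulus_grid[j], index = j)
}

#' Bayes update of a Psi staircase
#'
#' Multiplies the posterior by the Weibull likelihood of the observed
#' response at every lattice point, renormalizes, and appends the trial (with
#' the posterior-mean alpha as the running threshold estimate) to the
#' history.
#'
#' @param state A [psi_init()] state.
#' @param stimulus The presented stimulus; must be a stimulus-grid value.
#' @param correct Logical: was the response correct?
#' @return The updated `psi_state`.
#' @export
psi_update <- function(state, stimulus, correct) {
  stopifnot(inherits(state, "psi_state"))
  j <- which(abs(state$stimulus_grid - stimulus) <=
               1e-9 * max(1, abs(stimulus)))[1L]
  if (is.na(j)) {
    stop("psi_update: stimulus is not on the stimulus grid", call. = FALSE)
  }
  lik <- if (isTRUE(as.logical(correct))) state$P[, j] else 1 - state$P[, j]
  post <- state$posterior * lik
  tot <- sum(post)
  if (tot <= 0) {
    stop("psi_update: zero total likelihood (invalid lattice)", call. = FALSE)
  }
  state$posterior <- post / tot
  est <- sum(state$posterior * state$theta$alpha)
  state$history <- rbind(state$history, data.frame(
    trial = nrow(state$history) + 1L, stimulus = state$stimulus_grid[j],
    correct = as.integer(as.logical(correct)), estimate = est))
  state
}

#' Simulate a full adaptive staircase on a known observer
#'
#' Alternates [psi_select()], a Bernoulli response draw from the observer's
#' Weibull function, and [psi_update()] for `n_trials` trials (25 in the
#' study), then fits a Weibull to the trial data, reads out the 80%
#' threshold, and applies the staircase quality rule. Fully reproducible
#' given `seed`.
#'
#' @param observer A [psychometric_model()] describing the simulated
#'   observer.
#' @param n_trials Number of trials (default 25).
#' @param seed RNG seed for the response draws.
#' @param state Optional pre-built [psi_init()] state; defaults to the
#'   standard lattice for the observer's stimulus dimension.
#' @param condition Condition label stored on the record.
#' @param criterion Performance criterion for the threshold readout
#'   (default 0.8).
#' @return An object of class `staircase_record`: a list with `condition`,
#'   `trials` (history data frame), `fit`, `threshold_80`, `qc_ratio`,
#'   `flagged`, `degenerate` and `seed`.
#' @export
#' @examples
#' obs <- observer_with_threshold(120)
#' rec <- run_staircase(obs, seed = 1)
#' rec$threshold_80
run_staircase <- function(observer, n_trials = 25, seed,
                          state = NULL, condition = "", criterion = 0.8) {
  stopifnot(inherits(observer, "psychometric_model"))
  if (missing(seed)) stop("run_staircase: a seed is required", call. = FALSE)
  if (is.null(state)) state <- psi_init(mode = observer$stimulus_dimension)
  # local RNG stream so the simulation never disturbs the caller's RNG
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u <- stats::runif(n_trials)
  # lean inner loop: same selection/update rules as psi_select/psi_update,
  # but without per-trial data-frame growth
  post <- state$posterior
  P <- state$P
  alpha_theta <- state$theta$alpha
  p_obs <- weibull_p(state$stimulus_grid, observer)
  idx <- integer(n_trials)
  corr <- integer(n_trials)
  est <- numeric(n_trials)
  logP <- state$logP
  log1mP <- state$log1mP
  for (i in seq_len(n_trials)) {
    eh <- psi_eh(post, P, logP, log1mP)
    j <- which(eh <= min(eh) + 1e-12)[1L]
    correct <- u[i] < p_obs[j]
    lik <- if (correct) P[, j] else 1 - P[, j]
    post <- post * lik
    post <- post / sum(post)
    idx[i] <- j
    corr[i] <- as.integer(correct)
    est[i] <- sum(post * alpha_theta)
  }
  state$posterior <- post
  state$history <- data.frame(trial = seq_len(n_trials),
                              stimulus = state$stimulus_grid[idx],
                              correct = corr, estimate = est)
  fit <- fit_weibull(state$history, gamma = state$gamma,
                     lambda = state$lambda,
                     stimulus_dimension = observer$stimulus_dimension)
  degenerate <- isTRUE(attr(fit, "degenerate"))
  thr <- if (degenerate) fit$alpha else threshold_at(fit, criterion)
  rec <- structure(list(
    condition = condition, trials = state$history, fit = fit,
    threshold_80 = thr, qc_ratio = NA_real_, flagged = NA,
    degenerate = degenerate, seed = seed, state = state
  ), class = "staircase_record")
  if (n_trials >= 15) {
    qc <- staircase_quality(rec)
    rec$qc_ratio <- qc$ratio
    rec$flagged <- qc$flagged
  }
  rec
}

#' @export
print.staircase_record <- function(x, ...) {
  cat(sprintf(
    "<staircase_record> %s: %d trials, threshold(80%%) = %.4g, qc ratio = %.3g%s%s\n",
    if (nzchar(x$condition)) x$condition else "<unnamed>",
    nrow(x$trials), x$threshold_80, x$qc_ratio,
    if (isTRUE(x$flagged)) " [flagged]" else "",
    if (isTRUE(x$degenerate)) " [degenerate fit]" else ""))
  invisible(x)
}
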