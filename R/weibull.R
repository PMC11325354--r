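#' Psychometric model (Weibull with fixed guess and lapse rates)
#'
#' The psychometric function is
#' `psi(x) = gamma + (1 - gamma - lambda) * (1 - exp(-(x / alpha)^beta))`,
#' mapping stimulus magnitude (duration in ms, or Michelson contrast) to the
#' probability of a correct response. Guess and lapse rates are fixed at 50%
#' and 4% for the two-alternative tasks modeled here.
#'
#' @param alpha Location parameter (stimulus units, `> 0`).
#' @param beta Slope parameter (dimensionless, `> 0`).
#' @param gamma Guess rate (default 0.5).
#' @param lambda Lapse rate (default 0.04).
#' @param stimulus_dimension `"duration"` or `"contrast"`.
#' @return An object of class `psychometric_model`.
#' @export
#' @examples
#' m <- psychometric_model(alpha = 100, beta = 3)
#' weibull_p(100, m)
psychometric_model <- function(alpha, beta, gamma = 0.5, lambda = 0.04,
                               stimulus_dimension = c("duration", "contrast")) {
  stimulus_dimension <- match.arg(stimulus_dimension)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("psychometric_model: alpha must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0) {
    stop("psychometric_model: beta must be a single positive number",
         call. = FALSE)
  }
  if (gamma < 0 || lambda < 0 || gamma >= 1 - lambda) {
    stop("psychometric_model: need 0 <= gamma < 1 - lambda", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
                 stimulus_dimension = stimulus_dimension),
            class = "psychometric_model")
}

#' @export
print.psychometric_model <- function(x, ...) {
  cat(sprintf(
    "<psychometric_model> Weibull, %s mode: alpha = %.4g, beta = %.3g, gamma = %g, lambda = %g\n",
    x$stimulus_dimension, x$alpha, x$beta, x$gamma, x$lambda))
  if (isTRUE(attr(x, "degenerate"))) cat("  (degenerate boundary fit)\n")
  invisible(x)
}

#' Probability correct under a Weibull psychometric model
#'
#' @param x Stimulus value(s), `> 0`.
#' @param model A [psychometric_model()].
#' @return Probability correct, in `[gamma, 1 - lambda)`.
#' @export
weibull_p <- function(x, model) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("weibull_p: stimulus values must be positive and finite",
         call. = FALSE)
  }
  model$gamma + (1 - model$gamma - model$lambda) *
    (1 - exp(-(x / model$alpha)^model$beta))
}

#' Stimulus value at a criterion performance level
#'
#' Exact inverse of the Weibull psychometric function; the study's thresholds
#' are read out at 80% correct.
#'
#' @param model A [psychometric_model()].
#' @param p Criterion probability, strictly between `gamma` and `1 - lambda`.
#' @return The stimulus value `x` with `weibull_p(x, model) == p`.
#' @export
#' @examples
#' m <- psychometric_model(alpha = 100, beta = 3)
#' threshold_at(m, 0.8)
threshold_at <- function(model, p = 0.8) {
  if (p <= model$gamma || p >= 1 - model$lambda) {
    stop(sprintf(
      "threshold_at: criterion p = %g must lie strictly between gamma = %g and 1 - lambda = %g",
      p, model$gamma, 1 - model$lambda), call. = FALSE)
  }
  q <- (p - model$gamma) / (1 - model$gamma - model$lambda)
  model$alpha * (-log(1 - q))^(1 / model$beta)
}

#' Observer with a specified threshold
#'
#' Convenience constructor: builds a Weibull observer whose performance
#' crosses `p` exactly at `threshold`, by inverting [threshold_at()].
#'
#' @param threshold Stimulus value at the criterion level.
#' @param p Criterion probability (default 0.8).
#' @inheritParams psychometric_model
#' @return A [psychometric_model()].
#' @export
observer_with_threshold <- function(threshold, beta = 3, p = 0.8,
                                    gamma = 0.5, lambda = 0.04,
                                    stimulus_dimension = "duration") {
  q <- (p - gamma) / (1 - gamma - lambda)
  alpha <- threshold / (-log(1 - q))^(1 / beta)
  psychometric_model(alpha, beta, gamma, lambda, stimulus_dimension)
}

#' Maximum-likelihood Weibull fit with fixed guess and lapse rates
#'
#' Fits `alpha` and `beta` by maximizing the Bernoulli likelihood of the
#' responses, optimizing over `log(alpha)` and `log(beta)`. Guess and lapse
#' rates are fixed (50% / 4% by default), matching the study's fitting
#' procedure for individual staircases.
#'
#' @param trials A data frame with columns `stimulus` (positive values) and
#'   `response` (0/1 or logical).
#' @param gamma,lambda Fixed guess and lapse rates.
#' @param stimulus_dimension Passed through to the returned model.
#' @return A [psychometric_model()]; attribute `degenerate` is `TRUE` for
#'   boundary fits (all responses correct or all incorrect).
#' @export
fit_weibull <- function(trials, gamma = 0.5, lambda = 0.04,
                        stimulus_dimension = "duration") {
  stim <- trials$stimulus
  resp <- trials$response
  if (is.null(resp)) resp <- trials$correct  # staircase histories
  resp <- as.numeric(resp)
  if (length(resp) != length(stim) || length(resp) == 0L) {
    stop("fit_weibull: need one response per stimulus", call. = FALSE)
  }
  if (length(stim) < 2L || length(unique(stim)) < 2L) {
    stop("fit_weibull: need responses at >= 2 distinct stimulus levels",
         call. = FALSE)
  }
  if (any(stim <= 0)) stop("fit_weibull: stimuli must be positive",
                           call. = FALSE)
  if (!all(resp %in% c(0, 1))) {
    stop("fit_weibull: responses must be 0/1", call. = FALSE)
  }
  if (all(resp == 1) || all(resp == 0)) {
    # no information about the transition point: boundary fit
    alpha <- if (all(resp == 1)) min(stim) else max(stim)
    m <- psychometric_model(alpha, beta = 3, gamma = gamma, lambda = lambda,
                            stimulus_dimension = stimulus_dimension)
    attr(m, "degenerate") <- TRUE
    return(m)
  }
  negll <- function(par) {
    alpha <- exp(par[1]); beta <- exp(par[2])
    p <- gamma + (1 - gamma - lambda) * (1 - exp(-(stim / alpha)^beta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(resp * log(p) + (1 - resp) * log(1 - p))
  }
  # start at the geometric mid of the sampled range with a moderate slope
  start <- c(log(exp(mean(log(range(stim))))), log(3))
  fit <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  fit2 <- tryCatch(
    stats::optim(fit$par, negll, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) fit)
  if (fit2$value <= fit$value) fit <- fit2
  m <- psychometric_model(exp(fit$par[1]), exp(fit$par[2]), gamma, lambda,
                          stimulus_dimension = stimulus_dimension)
  attr(m, "degenerate") <- FALSE
  m
}
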