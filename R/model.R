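# Divisive normalization model with a spatial top-down gain field.
#
# All fields live on a 1-D spatial grid (model units). The stimulus drive is
# the boxcar profile of the stimulus (height = contrast) convolved with a
# unit-area Gaussian of SD w_E; the attended drive is multiplied by the
# attention field; the suppressive drive is the attended drive convolved with
# a broader unit-area Gaussian of SD w_S; the response is the pointwise ratio
# E_att / (S + sigma). Predicted duration thresholds are k_scale / peak(R).

model_grid <- function(params) {
  seq(-params$grid_extent, params$grid_extent, by = params$grid_step)
}

# Unit-area Gaussian kernel sampled on the grid step; discretely normalized
# so convolution preserves the integral of its input exactly.
gauss_kernel <- function(w, step) {
  half <- ceiling(6 * w / step)
  xk <- (-half:half) * step
  g <- exp(-xk^2 / (2 * w^2))
  g / (sum(g) * step)
}

# Linear convolution with a symmetric kernel, trimmed to the input support.
# FFT-based with zero padding to a highly composite length.
conv_same <- function(f, kernel, step) {
  n <- length(f)
  m <- length(kernel)
  half <- (m - 1L) %/% 2L
  L <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  fa <- c(f, numeric(L - n))
  ka <- c(kernel, numeric(L - m))
  full <- Re(stats::fft(stats::fft(fa) * stats::fft(ka), inverse = TRUE)) /
    L * step
  full[(half + 1L):(half + n)]
}

# Boxcar profile of the stimulus on the model grid: each component deposits
# its contrast on the mirrored radial support {x : inner <= |x - c| <= outer}.
# Edge cells carry the fractional overlap of the support with the cell, so the
# discrete integral equals contrast * support width exactly and predictions
# are stable under grid refinement.
stimulus_profile <- function(spec, params) {
  x <- model_grid(params)
  step <- params$grid_step
  upd <- params$units_per_degree
  prof <- numeric(length(x))
  margin <- 3 * params$w_S
  cell_cover <- function(lo, hi) {
    # fraction of each grid cell [x - step/2, x + step/2] inside [lo, hi]
    pmax(0, pmin(x + step / 2, hi) - pmax(x - step / 2, lo)) / step
  }
  for (i in seq_along(spec$components)) {
    cmp <- spec$components[[i]]
    ctr <- cmp$center_deg * upd
    outer <- cmp$outer_deg * upd
    inner <- cmp$inner_deg * upd
    if (ctr + outer + margin > params$grid_extent ||
        ctr - outer - margin < -params$grid_extent) {
      stop(sprintf(paste0("stimulus_drive: component %d (outer radius %g deg)",
                          " extends beyond the grid; enlarge grid_extent so it",
                          " covers the stimulus plus 3*w_S"),
                   i, cmp$outer_deg), call. = FALSE)
    }
    cover <- cell_cover(ctr - outer, ctr + outer)
    if (inner > 0) cover <- cover - cell_cover(ctr - inner, ctr + inner)
    prof <- prof + cmp$contrast * cover
  }
  prof
}

#' Excitatory stimulus drive
#'
#' Convolves the stimulus's boxcar contrast profile with a unit-area Gaussian
#' of standard deviation `w_E`. Because the kernel has unit area, the spatial
#' integral of the drive equals contrast times boxcar support width.
#'
#' @param spec A [stimulus_spec()].
#' @param params A [model_params()].
#' @return A list with grid `x` and drive field `E`.
#' @export
stimulus_drive <- function(spec, params) {
  stopifnot(inherits(spec, "stimulus_spec"))
  validate_model_params(params)
  prof <- stimulus_profile(spec, params)
  E <- conv_same(prof, gauss_kernel(params$w_E, params$grid_step),
                 params$grid_step)
  E[E < 0] <- 0  # clip FFT round-off
  list(x = model_grid(params), E = E)
}

#' Attention (top-down gain) field
#'
#' A Gaussian gain bump of width `w_A` and amplitude `g_A` above a baseline
#' gain of 1, centered on the target (first) component. The gain never drops
#' below baseline.
#'
#' @inheritParams stimulus_drive
#' @return A list with grid `x` and gain field `A`.
#' @export
attention_field <- function(spec, params) {
  stopifnot(inherits(spec, "stimulus_spec"))
  validate_model_params(params)
  x <- model_grid(params)
  ctr <- spec$components[[1L]]$center_deg * params$units_per_degree
  A <- 1 + params$g_A * exp(-(x - ctr)^2 / (2 * params$w_A^2))
  list(x = x, A = A)
}

#' Population response of the normalization model
#'
#' Computes the attended drive `E_att = A * E`, the suppressive drive
#' `S = E_att (*) G(w_S)` (unit-area Gaussian convolution), and the response
#' field `R = E_att / (S + sigma)`; the model's scalar readout is the maximum
#' of `R` over the grid.
#'
#' @inheritParams stimulus_drive
#' @return An object of class `population_response`: a list with `x`, `E`,
#'   `A`, `E_att`, `S`, `R` and `peak`.
#' @export
#' @examples
#' r <- population_response(grating_stimulus(0.5, 0.98), model_params())
#' r$peak
population_response <- function(spec, params) {
  drv <- stimulus_drive(spec, params)
  att <- attention_field(spec, params)
  E_att <- att$A * drv$E
  S <- conv_same(E_att, gauss_kernel(params$w_S, params$grid_step),
                 params$grid_step)
  S[S < 0] <- 0
  R <- E_att / (S + params$sigma)
  structure(list(x = drv$x, E = drv$E, A = att$A, E_att = E_att, S = S,
                 R = R, peak = max(R), label = spec$label),
            class = "population_response")
}

#' @export
print.population_response <- function(x, ...) {
  cat("<population_response>",
      sprintf("label: %s", if (nzchar(x$label)) x$label else "<none>"),
      sprintf("grid: %d points on [%g, %g]", length(x$x), min(x$x), max(x$x)),
      sprintf("peak response: %.6g at x = %g", x$peak, x$x[which.max(x$R)]),
      sep = "\n  ")
  cat("\n")
  invisible(x)
}

#' Predicted duration threshold
#'
#' Thresholds are assumed inversely proportional to the peak population
#' response: `k_scale / peak(R)`. A single scaling factor applies across all
#' stimulus conditions.
#'
#' @inheritParams stimulus_drive
#' @return Predicted threshold in milliseconds.
#' @export
predict_threshold <- function(spec, params) {
  resp <- population_response(spec, params)
  if (resp$peak <= 0) {
    stop("predict_threshold: undefined threshold (peak response is zero; ",
         "zero-contrast stimulus?)", call. = FALSE)
  }
  params$k_scale / resp$peak
}

#' Predicted thresholds over a condition grid
#'
#' Evaluates the model over the cartesian product of sizes and contrasts
#' (single-grating conditions) and, optionally, a set of center-plus-surround
#' gap conditions at `gap_contrast`.
#'
#' @param sizes Stimulus diameters in degrees.
#' @param contrasts Michelson contrasts.
#' @param gaps Optional gap sizes in degrees for the annulus configuration.
#' @param params A [model_params()].
#' @param gap_contrast Contrast used for the gap conditions (default 0.98).
#' @param target_size_deg Target diameter for the gap conditions.
#' @return A data frame with one row per condition: `label`, `size_deg`,
#'   `contrast`, `gap_deg`, `peak`, `threshold_ms`.
#' @export
#' @examples
#' predict_condition_grid(c(0.5, 1.5, 6), c(0.03, 0.98), params = model_params())
predict_condition_grid <- function(sizes = c(0.5, 1.5, 6),
                                   contrasts = c(0.03, 0.98),
                                   gaps = NULL,
                                   params = model_params(),
                                   gap_contrast = 0.98,
                                   target_size_deg = 0.5) {
  if (length(sizes) == 0L || length(contrasts) == 0L) {
    stop("predict_condition_grid: sizes and contrasts must be non-empty",
         call. = FALSE)
  }
  rows <- list()
  for (ct in contrasts) {
    for (sz in sizes) {
      if (!is.finite(sz) || sz <= 0) {
        stop(sprintf("predict_condition_grid: invalid size %g", sz),
             call. = FALSE)
      }
      spec <- grating_stimulus(sz, ct)
      resp <- population_response(spec, params)
      rows[[length(rows) + 1L]] <- data.frame(
        label = spec$label, size_deg = sz, contrast = ct, gap_deg = NA_real_,
        peak = resp$peak, threshold_ms = params$k_scale / resp$peak,
        stringsAsFactors = FALSE
      )
    }
  }
  for (gp in gaps %||% numeric(0)) {
    spec <- annulus_stimulus(gp, contrast = gap_contrast,
                             target_size_deg = target_size_deg)
    resp <- population_response(spec, params)
    rows[[length(rows) + 1L]] <- data.frame(
      label = spec$label, size_deg = target_size_deg, contrast = gap_contrast,
      gap_deg = gp, peak = resp$peak,
      threshold_ms = params$k_scale / resp$peak, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Compare predictions under two parameter settings
#'
#' Evaluates the same condition grid under `params_a` and `params_b` and
#' tabulates per-condition differences. Used for the excitatory-width
#' (3 vs 4.5) and attention-width (3 vs 7) comparisons and for sweeps of the
#' suppressive pooling width.
#'
#' @param params_a,params_b Two [model_params()] settings.
#' @param conditions A data frame with columns `label`, `size_deg`,
#'   `contrast` and optionally `gap_deg` (NA for single gratings), as produced
#'   by [predict_condition_grid()]; or NULL for the default 3 x 2 grid.
#' @return A data frame with both predictions, their difference and the
#'   relative difference `(b - a) / a`.
#' @export
parameter_contrast <- function(params_a, params_b, conditions = NULL) {
  validate_model_params(params_a)
  validate_model_params(params_b)
  if (identical(unclass(params_a), unclass(params_b))) {
    warning("parameter_contrast: parameter settings are identical; ",
            "all differences will be zero", call. = FALSE)
  }
  if (is.null(conditions)) {
    conditions <- expand.grid(size_deg = c(0.5, 1.5, 6),
                              contrast = c(0.03, 0.98),
                              KEEP.OUT.ATTRS = FALSE)
    conditions$gap_deg <- NA_real_
    conditions$label <- sprintf("d%g_c%g", conditions$size_deg,
                                conditions$contrast)
  }
  if (is.null(conditions$gap_deg)) conditions$gap_deg <- NA_real_
  one <- function(row, params) {
    spec <- if (is.na(row$gap_deg)) {
      grating_stimulus(row$size_deg, row$contrast, label = row$label)
    } else {
      annulus_stimulus(row$gap_deg, contrast = row$contrast,
                       target_size_deg = row$size_deg, label = row$label)
    }
    predict_threshold(spec, params)
  }
  out <- conditions[, c("label", "size_deg", "contrast", "gap_deg")]
  out$threshold_a <- vapply(seq_len(nrow(conditions)), function(i)
    one(conditions[i, ], params_a), numeric(1))
  out$threshold_b <- vapply(seq_len(nrow(conditions)), function(i)
    one(conditions[i, ], params_b), numeric(1))
  out$diff <- out$threshold_b - out$threshold_a
  out$rel_diff <- out$diff / out$threshold_a
  rownames(out) <- NULL
  out
}

#' Response fields as a data frame
#'
#' Tidies a [population_response()] into a long-friendly table of the model
#' fields (for plotting or CSV export).
#'
#' @param resp A `population_response`.
#' @return A data frame with columns `x`, `E`, `A`, `E_att`, `S`, `R`.
#' @export
response_fields <- function(resp) {
  stopifnot(inherits(resp, "population_response"))
  data.frame(x = resp$x, E = resp$E, A = resp$A, E_att = resp$E_att,
             S = resp$S, R = resp$R)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
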