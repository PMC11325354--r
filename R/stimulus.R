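#' Model parameters for the normalization model
#'
#' Bundles the spatial and scaling parameters of the divisive normalization
#' model with top-down attentional gain. All spatial widths are expressed in
#' model units; stimulus geometry is given in degrees of visual angle and
#' converted through `units_per_degree`.
#'
#' @param w_E Standard deviation of the excitatory-drive Gaussian kernel
#'   (model units). The study's comparison values are 3 (narrow) and 4.5
#'   (wide); the default is their midpoint.
#' @param w_S Standard deviation of the suppressive-pool Gaussian kernel
#'   (model units). Must exceed `w_E`: the suppressive drive pools over a
#'   spatially broader region than the excitatory drive.
#' @param w_A Standard deviation of the attention (top-down gain) field
#'   (model units). Comparison values are 3 (narrow) and 7 (wide); default is
#'   their midpoint.
#' @param g_A Peak attentional gain above the baseline gain of 1
#'   (dimensionless, `>= 0`).
#' @param sigma Semisaturation constant added to the suppressive drive in the
#'   normalization denominator (drive units, `> 0`).
#' @param k_scale Scaling factor converting the reciprocal peak population
#'   response into milliseconds (ms x response units).
#' @param grid_extent Half-width of the spatial grid (model units).
#' @param grid_step Spatial sampling step (model units).
#' @param units_per_degree Conversion from degrees of visual angle to model
#'   units.
#'
#' @return An object of class `model_params` (a validated list).
#' @export
#' @examples
#' p <- model_params()
#' p$w_E
model_params <- function(w_E = 3.75,
                         w_S = 8,
                         w_A = 5,
                         g_A = 3,
                         sigma = 0.02,
                         k_scale = 76,
                         grid_extent = 70,
                         grid_step = 0.05,
                         units_per_degree = 5) {
  p <- list(
    w_E = w_E, w_S = w_S, w_A = w_A, g_A = g_A, sigma = sigma,
    k_scale = k_scale, grid_extent = grid_extent, grid_step = grid_step,
    units_per_degree = units_per_degree
  )
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("w_E", "w_S", "w_A", "sigma", "k_scale", "grid_extent",
              "grid_step", "units_per_degree")) {
    if (!num1(p[[f]]) || p[[f]] <= 0) {
      stop(sprintf("model_params: '%s' must be a single positive number", f),
           call. = FALSE)
    }
  }
  if (!num1(p$g_A) || p$g_A < 0) {
    stop("model_params: 'g_A' must be a single non-negative number",
         call. = FALSE)
  }
  if (p$w_S <= p$w_E) {
    stop("model_params: the suppressive pool must be spatially broader than ",
         "the excitatory drive (w_S > w_E)", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  widths (model units): w_E = %g, w_S = %g, w_A = %g\n",
              x$w_E, x$w_S, x$w_A))
  cat(sprintf("  attention gain g_A = %g, sigma = %g, k_scale = %g ms\n",
              x$g_A, x$sigma, x$k_scale))
  cat(sprintf("  grid: +/-%g units, step %g; %g units per degree\n",
              x$grid_extent, x$grid_step, x$units_per_degree))
  invisible(x)
}

#' Build a stimulus component
#'
#' A component is an annular (or, with `inner_deg = 0`, disk-shaped) grating
#' patch described by its radial extent and Michelson contrast. The spatial
#' profile used by the model is the 1-D radial cut through the component,
#' mirrored about its center.
#'
#' @param outer_deg Outer radius in degrees (`> inner_deg`).
#' @param inner_deg Inner radius in degrees (0 for a disk).
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param center_deg Center position in degrees (0 = fixation).
#' @param direction Motion direction label, metadata only.
#' @return A list of class `stim_component`.
#' @export
stim_component <- function(outer_deg, inner_deg = 0, contrast = 0.98,
                           center_deg = 0, direction = "left") {
  if (!is.numeric(contrast) || length(contrast) != 1L ||
      contrast < 0 || contrast > 1) {
    stop("stim_component: contrast must lie in [0, 1]", call. = FALSE)
  }
  if (inner_deg < 0 || outer_deg <= inner_deg) {
    stop("stim_component: need outer radius > inner radius >= 0",
         call. = FALSE)
  }
  structure(list(outer_deg = outer_deg, inner_deg = inner_deg,
                 contrast = contrast, center_deg = center_deg,
                 direction = direction),
            class = "stim_component")
}

#' Assemble a stimulus specification
#'
#' The first component is taken as the target: the attention field is centered
#' on it (fixation coincides with the target center in all experiments
#' modeled here).
#'
#' @param ... `stim_component` objects; the first is the target.
#' @param label Condition label carried through prediction tables.
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(..., label = "") {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1]]) &&
      !inherits(comps[[1]], "stim_component")) {
    comps <- comps[[1]]
  }
  if (length(comps) == 0L) {
    stop("stimulus_spec: at least one component is required", call. = FALSE)
  }
  for (cmp in comps) {
    if (!inherits(cmp, "stim_component")) {
      stop("stimulus_spec: all components must be stim_component objects",
           call. = FALSE)
    }
  }
  check_component_overlap(comps)
  structure(list(components = comps, label = label), class = "stimulus_spec")
}

# Components must not overlap radially when sharing a center; overlapping
# patches would double-count drive.
check_component_overlap <- function(comps) {
  if (length(comps) < 2L) return(invisible(TRUE))
  iv <- lapply(comps, function(cmp) {
    c(cmp$center_deg - cmp$outer_deg, cmp$center_deg + cmp$outer_deg,
      cmp$inner_deg, cmp$center_deg)
  })
  for (i in seq_along(comps)) {
    for (j in seq_along(comps)) {
      if (i >= j) next
      a <- comps[[i]]; b <- comps[[j]]
      if (a$center_deg == b$center_deg) {
        # concentric: radial intervals [inner, outer] must be disjoint
        if (max(a$inner_deg, b$inner_deg) < min(a$outer_deg, b$outer_deg)) {
          stop("stimulus_spec: components ", i, " and ", j,
               " overlap radially", call. = FALSE)
        }
      } else if (max(iv[[i]][1], iv[[j]][1]) < min(iv[[i]][2], iv[[j]][2])) {
        stop("stimulus_spec: components ", i, " and ", j, " overlap",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Single centered grating stimulus
#'
#' @param size_deg Stimulus diameter in degrees (the study used 0.5, 1.5 and
#'   6 degrees).
#' @param contrast Michelson contrast (3% low, 98% high in the study).
#' @param label Optional condition label; defaults to `"d<size>_c<contrast>"`.
#' @return A `stimulus_spec`.
#' @export
#' @examples
#' grating_stimulus(0.5, 0.98)
grating_stimulus <- function(size_deg, contrast, label = NULL) {
  if (is.null(label)) label <- sprintf("d%g_c%g", size_deg, contrast)
  stimulus_spec(stim_component(outer_deg = size_deg / 2, contrast = contrast),
                label = label)
}

#' Center-plus-surround (gap) stimulus
#'
#' The spatial-integration configuration: a small central target disk and a
#' same-contrast annular surround whose inner edge sits `gap_deg` beyond the
#' target's outer edge. The surround drifts in the same direction as the
#' target and therefore contributes to the same drive field.
#'
#' @param gap_deg Gap between the target's outer edge and the surround's
#'   inner edge, in degrees (the study used 0.5, 1.0, 1.5, 2.5, 4.5).
#' @param contrast Michelson contrast of target and surround.
#' @param target_size_deg Target diameter in degrees (default 0.5).
#' @param surround_outer_deg Outer radius of the surround in degrees
#'   (default 7.75).
#' @param label Optional condition label.
#' @return A `stimulus_spec`.
#' @export
annulus_stimulus <- function(gap_deg, contrast = 0.98, target_size_deg = 0.5,
                             surround_outer_deg = 7.75, label = NULL) {
  if (is.null(label)) label <- sprintf("gap%g", gap_deg)
  target_r <- target_size_deg / 2
  stimulus_spec(
    stim_component(outer_deg = target_r, contrast = contrast),
    stim_component(outer_deg = surround_outer_deg,
                   inner_deg = target_r + gap_deg, contrast = contrast),
    label = label
  )
}
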