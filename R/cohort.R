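# Synthetic study generator: parcel tables with a planted parietal/frontal
# structure, observer model parameters coupled to surface area, threshold
# data at two fidelities (noise-perturbed model predictions, or full
# trial-level adaptive staircases), and hMT+ block time courses.

#' Experiment-1 condition set
#'
#' Three sizes (0.5, 1.5, 6 degrees diameter) crossed with two Michelson
#' contrasts (3% and 98%).
#'
#' @return A data frame with `label`, `size_deg`, `contrast`, `gap_deg`.
#' @export
conditions_exp1 <- function() {
  data.frame(
    label = c("small_low", "medium_low", "large_low",
              "small_high", "medium_high", "large_high"),
    size_deg = rep(c(0.5, 1.5, 6), 2),
    contrast = rep(c(0.03, 0.98), each = 3),
    gap_deg = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Experiment-2 condition set (center + surround gaps)
#'
#' A 0.5-degree high-contrast target with a same-direction surround at five
#' gap sizes, plus the no-surround control.
#'
#' @return A data frame with `label`, `size_deg`, `contrast`, `gap_deg`.
#' @export
conditions_exp2 <- function() {
  gaps <- c(0.5, 1, 1.5, 2.5, 4.5)
  data.frame(
    label = c(sprintf("gap_%g", gaps), "no_surround"),
    size_deg = 0.5, contrast = 0.98, gap_deg = c(gaps, NA_real_),
    stringsAsFactors = FALSE
  )
}

# Deterministic 31-bit sub-seed derived from a master seed and a text tag,
# so every table draws from its own reproducible stream. All intermediate
# products stay below 2^53, so the arithmetic is exact in doubles.
derive_seed <- function(seed, tag) {
  h <- 5381
  for (ch in utf8ToInt(tag)) {
    h <- (h * 33 + ch) %% 67108859
  }
  r <- (as.numeric(seed) %% 2147483647) * 48271 + h * 31627
  r <- (r %% 2147483647) * 48271 %% 2147483647   # one Lehmer scramble
  as.integer(r %% 2147483646 + 1)
}

#' Parcel catalogue for the synthetic atlas
#'
#' A synthetic stand-in for a 360-parcel (180 per hemisphere) multimodal
#' parcellation. It contains the six designated parcels of the study's
#' parietal/frontal regions — right 7AL, VIP, LIPd, IP1, IP2 and left 11l —
#' plus generically named filler parcels.
#'
#' @param n_per_hemi Parcels per hemisphere (default 180).
#' @return A data frame with `hemisphere` and `parcel`.
#' @export
parcel_catalogue <- function(n_per_hemi = 180) {
  designated_R <- c("7AL", "VIP", "LIPd", "IP1", "IP2")
  designated_L <- "11l"
  fill <- function(named, n) {
    c(named, sprintf("ROI_%03d", seq_len(n - length(named))))
  }
  rbind(
    data.frame(hemisphere = "L", parcel = fill(designated_L, n_per_hemi),
               stringsAsFactors = FALSE),
    data.frame(hemisphere = "R", parcel = fill(designated_R, n_per_hemi),
               stringsAsFactors = FALSE)
  )
}

#' Configuration of a synthetic cohort
#'
#' Defaults define the emulated study conditions: 62 subjects, a 360-parcel
#' catalogue with hemispheric shares of roughly 0.5-1.5%, a correlated
#' right-parietal parcel cluster, negative couplings from parietal share to
#' excitatory width and from frontal share to attention width, multiplicative
#' lognormal threshold noise, and block-design hMT+ time courses.
#'
#' @param n_subjects Number of subjects (default 62).
#' @param catalogue Parcel catalogue data frame ([parcel_catalogue()]).
#' @param parcel_spread_sdlog Between-parcel spread of mean log-area, setting
#'   the 0.5-1.5% share range.
#' @param subject_sdlog Between-subject SD of log parcel area.
#' @param global_sdlog Between-subject SD of overall brain scale (cancels in
#'   shares).
#' @param parietal_rho Within-cluster correlation of the five right-parietal
#'   parcels (default 0.6); the frontal parcel is drawn independently.
#' @param slope_wE Change in excitatory width per SD of summed parietal share
#'   (`<= 0`).
#' @param slope_wA Change in attention width per SD of frontal share
#'   (`<= 0`).
#' @param threshold_noise_sdlog SD of multiplicative lognormal threshold
#'   noise (fast fidelity).
#' @param observer_beta Weibull slope of simulated observers (full fidelity).
#' @param contrast_threshold_meanlog,contrast_threshold_sdlog Lognormal
#'   parameters of the (model-independent) contrast-detection thresholds.
#' @param fmri_noise_sd Per-sample Gaussian noise SD of the percent-signal-
#'   change time courses.
#' @param fmri_subject_sdlog Between-subject lognormal SD of overall hMT+
#'   responsiveness (hemodynamic/vascular variation unrelated to the planted
#'   couplings).
#' @param fmri_amp_scale Percent signal change per unit peak model response.
#' @param fd_spike_prob Per-TR probability of a framewise-displacement spike
#'   above 0.9 mm.
#' @param n_runs fMRI runs per subject.
#' @param blocks_per_condition Blocks per contrast condition per run.
#' @param model Shared [model_params()] defaults; `w_E`/`w_A` are overridden
#'   per subject.
#' @param fidelity `"fast"` (noise-perturbed model predictions) or `"full"`
#'   (trial-level Psi staircases).
#' @param experiments Subset of `c("exp1", "exp2", "exp5", "fmri")` to
#'   generate.
#' @param seed Master seed; all randomness flows from it through derived
#'   per-table seeds.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 62,
                          catalogue = parcel_catalogue(),
                          parcel_spread_sdlog = 0.28,
                          subject_sdlog = 0.12,
                          global_sdlog = 0.08,
                          parietal_rho = 0.6,
                          slope_wE = -0.5,
                          slope_wA = -1.33,
                          threshold_noise_sdlog = 0.14,
                          observer_beta = 3,
                          contrast_threshold_meanlog = log(0.008),
                          contrast_threshold_sdlog = 0.25,
                          fmri_noise_sd = 0.35,
                          fmri_subject_sdlog = 0.13,
                          fmri_amp_scale = 0.65,
                          fd_spike_prob = 0.02,
                          n_runs = 2,
                          blocks_per_condition = 6,
                          model = model_params(),
                          fidelity = c("fast", "full"),
                          experiments = c("exp1", "exp2", "exp5", "fmri"),
                          seed = 1L) {
  fidelity <- match.arg(fidelity)
  experiments <- match.arg(experiments, several.ok = TRUE)
  if (n_subjects < 3) {
    stop("cohort_config: need at least 3 subjects", call. = FALSE)
  }
  if (slope_wE > 0 || slope_wA > 0) {
    stop("cohort_config: effect-size slopes must be <= 0 (larger share -> ",
         "narrower width)", call. = FALSE)
  }
  if (threshold_noise_sdlog < 0 || fmri_noise_sd < 0 ||
      fmri_subject_sdlog < 0 || fd_spike_prob < 0 || fd_spike_prob > 1) {
    stop("cohort_config: noise parameters out of range", call. = FALSE)
  }
  if (anyDuplicated(paste(catalogue$hemisphere, catalogue$parcel))) {
    stop("cohort_config: parcel catalogue has duplicate names",
         call. = FALSE)
  }
  validate_model_params(model)
  cfg <- list(
    n_subjects = as.integer(n_subjects), catalogue = catalogue,
    parcel_spread_sdlog = parcel_spread_sdlog,
    subject_sdlog = subject_sdlog, global_sdlog = global_sdlog,
    parietal_rho = parietal_rho, slope_wE = slope_wE, slope_wA = slope_wA,
    threshold_noise_sdlog = threshold_noise_sdlog,
    observer_beta = observer_beta,
    contrast_threshold_meanlog = contrast_threshold_meanlog,
    contrast_threshold_sdlog = contrast_threshold_sdlog,
    fmri_noise_sd = fmri_noise_sd, fmri_subject_sdlog = fmri_subject_sdlog,
    fmri_amp_scale = fmri_amp_scale,
    fd_spike_prob = fd_spike_prob, n_runs = as.integer(n_runs),
    blocks_per_condition = as.integer(blocks_per_condition),
    model = model, fidelity = fidelity, experiments = experiments,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d subjects, %d parcels, fidelity = %s, seed = %d\n",
    x$n_subjects, nrow(x$catalogue), x$fidelity, x$seed))
  cat(sprintf("  couplings: slope_wE = %g, slope_wA = %g; threshold noise sdlog = %g\n",
              x$slope_wE, x$slope_wA, x$threshold_noise_sdlog))
  cat(sprintf("  experiments: %s\n", paste(x$experiments, collapse = ", ")))
  invisible(x)
}

subject_ids <- function(n) sprintf("S%03d", seq_len(n))

#' Sample a synthetic parcel surface-area table
#'
#' Parcel areas are lognormal: a fixed per-parcel mean level (spread so
#' normalized shares land mostly between 0.2% and 2%), a subject-level
#' global brain-scale factor, and subject-by-parcel variation. The five
#' right-parietal parcels share a subject-level latent factor (within-cluster
#' correlation `parietal_rho`); the left-frontal parcel is drawn
#' independently of it, so parietal and frontal shares are uncorrelated by
#' construction.
#'
#' @param config A [cohort_config()].
#' @return A parcel table (`subject`, `hemisphere`, `parcel`, `area_mm2`).
#' @export
sample_parcel_table <- function(config) {
  cat <- config$catalogue
  n_parcel <- nrow(cat)
  n <- config$n_subjects
  ids <- subject_ids(n)
  par_members <- parietal_region()$members
  is_parietal <- paste(cat$hemisphere, cat$parcel) %in%
    paste(par_members$hemisphere, par_members$parcel)

  with_seed(derive_seed(config$seed, "parcel_table"), {
    # fixed parcel-level mean log-areas (drawn once per cohort)
    mu <- log(500) + config$parcel_spread_sdlog * stats::rnorm(n_parcel)
    global <- config$global_sdlog * stats::rnorm(n)      # brain scale
    latent <- stats::rnorm(n)                            # parietal factor
    eps <- matrix(stats::rnorm(n * n_parcel), n, n_parcel)
    rho <- config$parietal_rho
    z <- eps
    z[, is_parietal] <- sqrt(rho) * latent +
      sqrt(1 - rho) * eps[, is_parietal]
    area <- exp(sweep(config$subject_sdlog * z, 2, mu, "+") + global)
    data.frame(
      subject = rep(ids, times = n_parcel),
      hemisphere = rep(cat$hemisphere, each = n),
      parcel = rep(cat$parcel, each = n),
      area_mm2 = as.numeric(area),
      stringsAsFactors = FALSE
    )
  })
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  expr
}

#' Map surface-area shares to per-subject model parameters
#'
#' Standardizes the summed normalized parietal share and the frontal share
#' across the cohort and maps them linearly (slopes `<= 0`) onto the
#' excitatory width and the attention width, clipped to the comparison
#' ranges `[3, 4.5]` and `[3, 7]`: larger parietal share gives narrower
#' excitatory receptive fields, larger frontal share narrower top-down gain.
#' A subject at the cohort mean share sits at the midpoint of each range.
#'
#' @param table A parcel table.
#' @param config A [cohort_config()].
#' @return A data frame with `subject`, `z_parietal`, `z_frontal`, `w_E`,
#'   `w_A`.
#' @export
map_sa_to_params <- function(table, config) {
  table <- normalize_sa(table)
  par_sa <- region_sum(table, parietal_region())
  fro_sa <- region_sum(table, frontal_region())
  zp <- as.numeric(scale(par_sa))
  zf <- as.numeric(scale(fro_sa))
  w_E <- pmin(4.5, pmax(3, 3.75 + config$slope_wE * zp))
  w_A <- pmin(7, pmax(3, 5 + config$slope_wA * zf))
  data.frame(subject = names(par_sa), z_parietal = zp, z_frontal = zf,
             w_E = w_E, w_A = w_A, stringsAsFactors = FALSE)
}

subject_model <- function(config, w_E, w_A) {
  p <- config$model
  p$w_E <- w_E
  p$w_A <- w_A
  p
}

predict_for_conditions <- function(params, conditions, cache = NULL) {
  key <- sprintf("%.12g_%.12g", params$w_E, params$w_A)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  thr <- vapply(seq_len(nrow(conditions)), function(i) {
    row <- conditions[i, ]
    spec <- if (is.na(row$gap_deg)) {
      grating_stimulus(row$size_deg, row$contrast, label = row$label)
    } else {
      annulus_stimulus(row$gap_deg, contrast = row$contrast,
                       target_size_deg = row$size_deg, label = row$label)
    }
    predict_threshold(spec, params)
  }, numeric(1))
  names(thr) <- conditions$label
  if (!is.null(cache)) cache[[key]] <- thr
  thr
}

#' Simulate one observer's psychophysical session
#'
#' Fast fidelity perturbs each condition's model-predicted threshold with
#' multiplicative lognormal noise. Full fidelity builds a Weibull observer
#' whose 80% point equals the model prediction and runs four seeded 25-trial
#' Psi staircases per condition (the study interleaved one staircase per
#' condition in each of four runs), aggregating by the quality rule plus
#' median; if every staircase of a condition is flagged, the median of all
#' four is used as a fallback and the condition is marked.
#'
#' @param params A [model_params()] carrying the subject's `w_E`/`w_A`.
#' @param conditions A condition data frame (see [conditions_exp1()]).
#' @param config A [cohort_config()].
#' @param seed Seed for this session.
#' @return A data frame with `condition`, `threshold`, `truth`,
#'   `n_flagged`, `fallback`.
#' @export
simulate_observer_session <- function(params, conditions, config, seed) {
  truth <- predict_for_conditions(params, conditions)
  if (config$fidelity == "fast") {
    noise <- with_seed(seed, stats::rnorm(length(truth)))
    thr <- truth * exp(config$threshold_noise_sdlog * noise)
    return(data.frame(condition = conditions$label, threshold = thr,
                      truth = truth, n_flagged = 0L, fallback = FALSE,
                      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_along(truth), function(i) {
    obs <- observer_with_threshold(truth[i], beta = config$observer_beta)
    recs <- lapply(1:4, function(k) {
      run_staircase(obs, n_trials = 25,
                    seed = derive_seed(seed, sprintf("%s_run%d",
                                                     conditions$label[i], k)),
                    condition = conditions$label[i])
    })
    flg <- vapply(recs, function(r) isTRUE(r$flagged), logical(1))
    thr_all <- vapply(recs, `[[`, numeric(1), "threshold_80")
    fallback <- all(flg)
    thr <- if (fallback) stats::median(thr_all) else
      stats::median(thr_all[!flg])
    data.frame(condition = conditions$label[i], threshold = thr,
               truth = truth[i], n_flagged = sum(flg), fallback = fallback,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a complete synthetic study
#'
#' Composes the parcel table, the surface-area-to-parameter mapping, the
#' psychophysical sessions for the requested experiments and the synthetic
#' hMT+ block time courses into one reproducible dataset: regenerating with
#' the same configuration (which includes the master seed) gives an
#' identical dataset.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort_dataset` with elements `parcels`,
#'   `truth`, `thresholds_exp1`, `thresholds_exp2`, `thresholds_exp5`,
#'   `fmri`, and `provenance`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 8, experiments = "exp1", seed = 7)
#' ds <- generate_cohort(cfg)
#' head(ds$thresholds_exp1)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  parcels <- sample_parcel_table(config)
  truth <- map_sa_to_params(parcels, config)
  ids <- truth$subject
  cache <- new.env(parent = emptyenv())

  session_tables <- function(conditions, tag) {
    rows <- lapply(seq_along(ids), function(i) {
      params <- subject_model(config, truth$w_E[i], truth$w_A[i])
      tr <- predict_for_conditions(params, conditions, cache)
      if (config$fidelity == "fast") {
        noise <- with_seed(derive_seed(config$seed,
                                       sprintf("%s_%s", tag, ids[i])),
                           stats::rnorm(length(tr)))
        thr <- tr * exp(config$threshold_noise_sdlog * noise)
        data.frame(subject = ids[i], condition = conditions$label,
                   threshold = thr, truth = tr, n_flagged = 0L,
                   fallback = FALSE, stringsAsFactors = FALSE)
      } else {
        ses <- simulate_observer_session(
          params, conditions, config,
          seed = derive_seed(config$seed, sprintf("%s_%s", tag, ids[i])))
        cbind(subject = ids[i], ses, stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  }

  out <- list(parcels = parcels, truth = truth,
              thresholds_exp1 = NULL, thresholds_exp2 = NULL,
              thresholds_exp5 = NULL, fmri = NULL)
  if ("exp1" %in% config$experiments) {
    out$thresholds_exp1 <- session_tables(conditions_exp1(), "exp1")
  }
  if ("exp2" %in% config$experiments) {
    out$thresholds_exp2 <- session_tables(conditions_exp2(), "exp2")
  }
  if ("exp5" %in% config$experiments) {
    out$thresholds_exp5 <- with_seed(derive_seed(config$seed, "exp5"), {
      ct_true <- exp(config$contrast_threshold_meanlog +
                       config$contrast_threshold_sdlog *
                         stats::rnorm(length(ids)))
      meas <- ct_true * exp(config$threshold_noise_sdlog *
                              stats::rnorm(length(ids)))
      data.frame(subject = ids, condition = "contrast_detection",
                 threshold = meas, truth = ct_true, n_flagged = 0L,
                 fallback = FALSE, stringsAsFactors = FALSE)
    })
  }
  if ("fmri" %in% config$experiments) {
    out$fmri <- generate_fmri_timecourses(truth, config)
  }
  out$provenance <- list(config = config, seed = config$seed,
                         generated = "normgain::generate_cohort")
  class(out) <- "cohort_dataset"
  out
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects, seed %d, fidelity %s\n",
              length(unique(x$truth$subject)), x$provenance$seed,
              x$provenance$config$fidelity))
  for (nm in c("thresholds_exp1", "thresholds_exp2", "thresholds_exp5")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
    }
  }
  if (!is.null(x$fmri)) cat(sprintf("  fmri: %d blocks\n", length(x$fmri)))
  invisible(x)
}

# Canonical response shape of a block: zero over the pre-onset baseline,
# rise, plateau, undershoot; the mean over the 8-12 s samples is exactly 1,
# so the planted amplitude is recovered exactly in the noise-free case.
block_response_shape <- function() {
  c(0, 0, 0, 0.2, 0.7, 0.95, 1, 1.05, 0.95, 0.5, 0.2, 0.05)
}

#' Generate synthetic hMT+ block time courses
#'
#' Block responses are proportional to the model's peak population response
#' for a 2-degree grating at the block's contrast under each subject's
#' parameters — hence coupled to the attention width, and through it to
#' frontal surface area. Gaussian noise is added per sample; framewise
#' displacement traces carry occasional spikes above 0.9 mm; per-run hit
#' rates on the fixation task are drawn around 0.9.
#'
#' @param truth Per-subject parameter table from [map_sa_to_params()].
#' @param config A [cohort_config()].
#' @return A list of `block_timecourse` objects.
#' @export
generate_fmri_timecourses <- function(truth, config) {
  shape <- block_response_shape()
  contrasts <- c(low = 0.03, high = 0.98)
  blocks <- list()
  for (i in seq_len(nrow(truth))) {
    params <- subject_model(config, truth$w_E[i], truth$w_A[i])
    amp <- vapply(contrasts, function(ct) {
      config$fmri_amp_scale *
        population_response(grating_stimulus(2, ct), params)$peak
    }, numeric(1))
    sid <- truth$subject[i]
    blocks[[sid]] <- with_seed(derive_seed(config$seed,
                                           paste0("fmri_", sid)), {
      # subject-level responsiveness factor, independent of the couplings
      amp_s <- amp * exp(config$fmri_subject_sdlog * stats::rnorm(1))
      out <- list()
      for (run in seq_len(config$n_runs)) {
        hit_rate <- min(1, max(0, stats::rnorm(1, 0.9, 0.05)))
        for (cond in names(contrasts)) {
          for (b in seq_len(config$blocks_per_condition)) {
            psc <- amp_s[cond] * shape +
              config$fmri_noise_sd * stats::rnorm(12)
            raw <- 100 * (1 + psc / 100)
            fd <- abs(stats::rnorm(15, 0.12, 0.05))
            spikes <- stats::runif(15) < config$fd_spike_prob
            fd[spikes] <- stats::runif(sum(spikes), 0.95, 1.8)
            out[[length(out) + 1L]] <- block_timecourse(
              samples = raw, fd = fd, subject = sid, run = run,
              block = b, condition = cond, hit_rate = hit_rate,
              amplitude_true = unname(amp_s[cond]))
          }
        }
      }
      out
    })
  }
  unlist(blocks, recursive = FALSE, use.names = FALSE)
}
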