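# End-to-end pipeline and command-line dispatch: synthetic cohort ->
# psychophysical thresholds -> surface-area normalization -> parcel screen ->
# region-condition correlations -> fMRI quantification, with provenance.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort from the configuration, writes its tables, normalizes
#' the parcel surface areas, screens all parcels against the behavioral
#' average of the two smaller high-contrast conditions, tabulates the
#' region-by-condition correlations, splits subjects into extreme
#' surface-area groups, quantifies the fMRI blocks, and writes a provenance
#' record sufficient to regenerate everything.
#'
#' @param config A [cohort_config()], or a list as returned by
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param alpha Screening threshold (default 0.01).
#' @param split_mode `"thirds"` or `"halves"`.
#' @param screen_conditions Condition labels averaged into the screening
#'   behavioral measure.
#' @return Invisibly, a list with the cohort dataset and every derived
#'   table.
#' @export
run_pipeline <- function(config, out_dir,
                         alpha = 0.01,
                         split_mode = "thirds",
                         screen_conditions = c("small_high", "medium_high")) {
  if (!inherits(config, "cohort_config") && is.list(config) &&
      !is.null(config$cohort)) {
    alpha <- config$analysis$alpha %||% alpha
    split_mode <- config$analysis$split_mode %||% split_mode
    screen_conditions <- config$analysis$screen_conditions %||%
      screen_conditions
    config <- config$cohort
  }
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ds <- generate_cohort(config)
  parcels <- normalize_sa(ds$parcels)
  write_parcel_csv(parcels, file.path(out_dir, "parcels.csv"))
  utils::write.csv(ds$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)

  out <- list(dataset = ds)
  n_flagged_total <- 0L
  for (nm in c("thresholds_exp1", "thresholds_exp2", "thresholds_exp5")) {
    if (!is.null(ds[[nm]])) {
      write_threshold_csv(ds[[nm]], file.path(
        out_dir, paste0(sub("thresholds_", "thresholds_", nm), ".csv")))
      n_flagged_total <- n_flagged_total + sum(ds[[nm]]$n_flagged)
    }
  }

  if (!is.null(ds$thresholds_exp1)) {
    beh <- behavioral_summary(ds$thresholds_exp1, screen_conditions)
    screen <- screen_parcels(parcels, beh, alpha = alpha, return_all = TRUE)
    utils::write.csv(screen, file.path(out_dir, "screen.csv"),
                     row.names = FALSE)
    out$screen <- screen
    message(sprintf("screen: %d of %d parcels pass p < %g",
                    sum(screen$pass), nrow(screen), alpha))

    regions <- list(parietal_region(), frontal_region())
    corr <- condition_correlation_matrix(
      regions, conditions_exp1()$label, parcels, ds$thresholds_exp1)
    utils::write.csv(corr, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    out$correlations <- corr

    par_sa <- region_sum(parcels, parietal_region())
    fro_sa <- region_sum(parcels, frontal_region())
    groups <- data.frame(
      subject = names(par_sa),
      parietal_group = group_split(par_sa, split_mode),
      frontal_group = group_split(fro_sa, split_mode),
      stringsAsFactors = FALSE)
    utils::write.csv(groups, file.path(out_dir, "groups.csv"),
                     row.names = FALSE)
    out$groups <- groups
  }

  if (!is.null(ds$fmri)) {
    utils::write.csv(fmri_blocks_to_df(ds$fmri),
                     file.path(out_dir, "fmri_blocks.csv"),
                     row.names = FALSE)
    resp <- condition_response(ds$fmri)
    utils::write.csv(resp, file.path(out_dir, "fmri_response.csv"),
                     row.names = FALSE)
    out$fmri_response <- resp
    message(sprintf("fmri: %d of %d condition cells have retained blocks",
                    sum(!is.na(resp$response)), nrow(resp)))
  }

  write_provenance(out_dir, config, config$seed,
                   extra = list(n_subjects = config$n_subjects,
                                fidelity = config$fidelity,
                                n_flagged_staircases = n_flagged_total,
                                alpha = alpha, split_mode = split_mode,
                                screen_conditions = screen_conditions))
  invisible(out)
}

cli_usage <- function() {
  paste(
    "usage: normgain <subcommand> [options]",
    "",
    "subcommands:",
    "  predict            --out FILE [--conditions FILE]",
    "  simulate-staircase --seed N --out FILE [--trials N] [--mode duration|contrast] [--threshold X]",
    "  simulate-cohort    --seed N --out DIR [--config FILE]",
    "  fit-thresholds     --trials FILE --out FILE",
    "  qc-staircases      --trials FILE --out FILE",
    "  sa-normalize       --parcels FILE --out FILE",
    "  screen-parcels     --parcels FILE --thresholds FILE --out FILE [--alpha X]",
    "  correlate          --parcels FILE --thresholds FILE --out FILE",
    "  group-split        --parcels FILE --out FILE [--mode thirds|halves]",
    "  fmri-psc           --blocks FILE --out FILE",
    "  run-all            --seed N --out DIR [--config FILE]",
    sep = "\n")
}

cli_opts <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    if (i == length(argv)) stop("missing value for ", a, call. = FALSE)
    opts[[substring(a, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

load_cli_config <- function(opts) {
  cfgs <- if (!is.null(opts$config)) {
    read_pipeline_config(opts$config)
  } else {
    list(cohort = cohort_config(), analysis = list())
  }
  if (!is.null(opts$seed)) cfgs$cohort$seed <- as.integer(opts$seed)
  cfgs
}

#' Command-line dispatch
#'
#' Entry point for the shell interface, e.g.
#' `Rscript -e 'quit(status = normgain::cli_dispatch(commandArgs(TRUE)))' run-all --seed 1 --out out/`.
#' Returns (rather than calls) the exit status so it is testable: 0 on
#' success, 1 on validation/processing failure, 2 on usage errors.
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Integer exit status.
#' @export
cli_dispatch <- function(argv) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help", "help")) {
    message(cli_usage())
    return(if (length(argv) == 0) 2L else 0L)
  }
  cmd <- argv[1]
  known <- c("predict", "simulate-staircase", "simulate-cohort",
             "fit-thresholds", "qc-staircases", "sa-normalize",
             "screen-parcels", "correlate", "group-split", "fmri-psc",
             "run-all")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd, "\n", cli_usage())
    return(2L)
  }
  opts <- tryCatch(cli_opts(argv[-1]),
                   error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", cli_usage())
    return(2L)
  }
  res <- tryCatch({
    switch(cmd,
      "predict" = {
        cond <- if (!is.null(opts$conditions)) {
          utils::read.csv(opts$conditions, stringsAsFactors = FALSE)
        } else NULL
        params <- model_params()
        tab <- if (is.null(cond)) {
          predict_condition_grid(params = params)
        } else {
          if (is.null(cond$gap_deg)) cond$gap_deg <- NA_real_
          pc <- parameter_contrast(params, params, conditions = cond)
          data.frame(label = pc$label, size_deg = pc$size_deg,
                     contrast = pc$contrast, gap_deg = pc$gap_deg,
                     threshold_ms = pc$threshold_a)
        }
        utils::write.csv(tab, opts$out, row.names = FALSE)
      },
      "simulate-staircase" = {
        thr <- as.numeric(opts$threshold %||% 120)
        mode <- opts$mode %||% "duration"
        obs <- observer_with_threshold(
          if (mode == "contrast" && is.null(opts$threshold)) 0.01 else thr,
          stimulus_dimension = mode)
        rec <- run_staircase(obs, n_trials = as.integer(opts$trials %||% 25),
                             seed = as.integer(opts$seed))
        utils::write.csv(cbind(rec$trials, threshold_80 = rec$threshold_80,
                               qc_ratio = rec$qc_ratio,
                               flagged = rec$flagged),
                         opts$out, row.names = FALSE)
      },
      "simulate-cohort" = {
        cfgs <- load_cli_config(opts)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        ds <- generate_cohort(cfgs$cohort)
        write_parcel_csv(ds$parcels, file.path(opts$out, "parcels.csv"))
        utils::write.csv(ds$truth, file.path(opts$out, "truth.csv"),
                         row.names = FALSE)
        for (nm in c("thresholds_exp1", "thresholds_exp2",
                     "thresholds_exp5")) {
          if (!is.null(ds[[nm]])) {
            write_threshold_csv(ds[[nm]],
                                file.path(opts$out, paste0(nm, ".csv")))
          }
        }
        if (!is.null(ds$fmri)) {
          utils::write.csv(fmri_blocks_to_df(ds$fmri),
                           file.path(opts$out, "fmri_blocks.csv"),
                           row.names = FALSE)
        }
        write_provenance(opts$out, cfgs$cohort, cfgs$cohort$seed)
      },
      "fit-thresholds" = {
        tab <- utils::read.csv(opts$trials, stringsAsFactors = FALSE)
        keys <- unique(tab[, c("subject", "condition", "staircase_id")])
        rows <- lapply(seq_len(nrow(keys)), function(i) {
          tr <- merge(tab, keys[i, ])
          fit <- fit_weibull(tr)
          data.frame(keys[i, ],
                     threshold_80 = if (isTRUE(attr(fit, "degenerate")))
                       NA_real_ else threshold_at(fit, 0.8),
                     alpha = fit$alpha, beta = fit$beta)
        })
        utils::write.csv(do.call(rbind, rows), opts$out, row.names = FALSE)
      },
      "qc-staircases" = {
        tab <- utils::read.csv(opts$trials, stringsAsFactors = FALSE)
        keys <- unique(tab[, c("subject", "condition", "staircase_id")])
        rows <- lapply(seq_len(nrow(keys)), function(i) {
          tr <- merge(tab, keys[i, ])
          est <- tr$running_estimate %||% tr$estimate
          qc <- staircase_quality(list(trials = data.frame(estimate = est)))
          data.frame(keys[i, ], qc_ratio = qc$ratio, flagged = qc$flagged)
        })
        utils::write.csv(do.call(rbind, rows), opts$out, row.names = FALSE)
      },
      "sa-normalize" = {
        tab <- normalize_sa(read_parcel_csv(opts$parcels))
        write_parcel_csv(tab, opts$out)
      },
      "screen-parcels" = {
        parcels <- read_parcel_csv(opts$parcels)
        thr <- read_threshold_csv(opts$thresholds)
        beh <- behavioral_summary(thr, unique(thr$condition)[1])
        if (!is.null(opts$conditions)) {
          beh <- behavioral_summary(thr, strsplit(opts$conditions,
                                                  ",")[[1]])
        }
        scr <- screen_parcels(parcels, beh,
                              alpha = as.numeric(opts$alpha %||% 0.01),
                              return_all = TRUE)
        utils::write.csv(scr, opts$out, row.names = FALSE)
      },
      "correlate" = {
        parcels <- read_parcel_csv(opts$parcels)
        thr <- read_threshold_csv(opts$thresholds)
        corr <- condition_correlation_matrix(
          list(parietal_region(), frontal_region()),
          unique(thr$condition), parcels, thr)
        utils::write.csv(corr, opts$out, row.names = FALSE)
      },
      "group-split" = {
        parcels <- read_parcel_csv(opts$parcels)
        par_sa <- region_sum(parcels, parietal_region())
        fro_sa <- region_sum(parcels, frontal_region())
        mode <- opts$mode %||% "thirds"
        utils::write.csv(data.frame(
          subject = names(par_sa),
          parietal_group = group_split(par_sa, mode),
          frontal_group = group_split(fro_sa, mode)),
          opts$out, row.names = FALSE)
      },
      "fmri-psc" = {
        blocks <- df_to_fmri_blocks(
          utils::read.csv(opts$blocks, stringsAsFactors = FALSE))
        utils::write.csv(condition_response(blocks), opts$out,
                         row.names = FALSE)
      },
      "run-all" = {
        cfgs <- load_cli_config(opts)
        run_pipeline(cfgs, opts$out)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}
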