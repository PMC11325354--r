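# Readers and writers: FreeSurfer anatomical-stats tables, threshold and
# parcel CSVs, pipeline configuration and provenance JSON.

#' Read a FreeSurfer anatomical-stats table
#'
#' Parses the text dialect emitted by `mris_anatomical_stats` (and the
#' `aparcstats2table`-style variants): comment and header lines start with
#' `#`, a `# ColHeaders ...` line names the whitespace-delimited columns,
#' and each data row describes one parcel. The structure name and the
#' surface-area column (`SurfArea`) are extracted; the hemisphere is taken
#' from a `# hemi` header line or, failing that, from an `lh`/`rh` prefix in
#' the file name.
#'
#' @param path Path to the stats file.
#' @param subject Subject ID to attach; defaults to the file name stem.
#' @param hemisphere Override the detected hemisphere (`"L"`/`"R"`).
#' @return Parcel-table rows: `subject`, `hemisphere`, `parcel`, `area_mm2`.
#' @export
read_freesurfer_stats <- function(path, subject = NULL, hemisphere = NULL) {
  if (!file.exists(path)) stop("read_freesurfer_stats: no such file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (is.null(subject)) {
    subject <- sub("\\.stats$", "", basename(path))
  }
  if (is.null(hemisphere)) {
    hemi_line <- grep("^#\\s*hemi\\b", lines, value = TRUE)
    hemisphere <- if (length(hemi_line) > 0) {
      toupper(substr(trimws(sub("^#\\s*hemi\\b", "", hemi_line[1])), 1, 1))
    } else if (grepl("^lh", basename(path))) "L"
    else if (grepl("^rh", basename(path))) "R"
    else stop("read_freesurfer_stats: cannot determine hemisphere; pass ",
              "`hemisphere`", call. = FALSE)
  }
  hemisphere <- if (hemisphere %in% c("L", "LH")) "L" else "R"
  ch <- grep("^#\\s*ColHeaders", lines, value = TRUE)
  if (length(ch) == 0) {
    stop("read_freesurfer_stats: no '# ColHeaders' line found",
         call. = FALSE)
  }
  headers <- strsplit(trimws(sub("^#\\s*ColHeaders", "", ch[1])),
                      "\\s+")[[1]]
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(data_lines) == 0) {
    stop("read_freesurfer_stats: no data rows", call. = FALSE)
  }
  fields <- strsplit(trimws(data_lines), "\\s+")
  name_col <- match("StructName", headers)
  area_col <- match("SurfArea", headers)
  if (is.na(area_col) || is.na(name_col)) {
    stop("read_freesurfer_stats: required column missing; detected ",
         "columns: ", paste(headers, collapse = ", "), call. = FALSE)
  }
  parcel <- vapply(fields, `[[`, character(1), name_col)
  area <- as.numeric(vapply(fields, `[[`, character(1), area_col))
  if (anyDuplicated(parcel)) {
    stop("read_freesurfer_stats: duplicate parcel name(s): ",
         paste(unique(parcel[duplicated(parcel)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(subject = subject, hemisphere = hemisphere, parcel = parcel,
             area_mm2 = area, stringsAsFactors = FALSE)
}

#' Read and write threshold tables
#'
#' Long-format CSV with columns `subject`, `condition`, `threshold`
#' (positive; empty cells are preserved as missing). Duplicated
#' subject-condition cells and non-positive thresholds are rejected with the
#' offending row number.
#'
#' @param path CSV path.
#' @return A threshold table data frame.
#' @export
read_threshold_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "threshold")
  if (!all(need %in% names(tab))) {
    stop("read_threshold_csv: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(tab$threshold) & tab$threshold <= 0)
  if (length(bad) > 0) {
    stop("read_threshold_csv: non-positive threshold in data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(paste(tab$subject, tab$condition)))
  if (length(dup) > 0) {
    stop("read_threshold_csv: duplicate subject x condition in data row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  tab$subject <- as.character(tab$subject)
  tab
}

#' @rdname read_threshold_csv
#' @param table Threshold table to write.
#' @export
write_threshold_csv <- function(table, path) {
  need <- c("subject", "condition", "threshold")
  if (!all(need %in% names(table))) {
    stop("write_threshold_csv: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(table[, intersect(names(table), c(need, "truth"))],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write parcel tables
#'
#' CSV with columns `subject`, `hemisphere`, `parcel`, `area_mm2` (and
#' optionally `normalized`).
#'
#' @param path CSV path.
#' @return A parcel table.
#' @export
read_parcel_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$subject <- as.character(tab$subject)
  check_parcel_table(tab)
  tab
}

#' @rdname read_parcel_csv
#' @param table Parcel table to write.
#' @export
write_parcel_csv <- function(table, path) {
  check_parcel_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Flatten fMRI blocks to a data frame (and back)
#'
#' Serializable wide form of a list of [block_timecourse()] objects:
#' `sample_1..12` are the raw samples at t = -4..18 s and `fd_1..15` the
#' framewise-displacement window.
#'
#' @param blocks List of `block_timecourse` objects.
#' @return A data frame, one row per block.
#' @export
fmri_blocks_to_df <- function(blocks) {
  rows <- lapply(blocks, function(b) {
    smp <- as.list(stats::setNames(b$samples, sprintf("sample_%d", 1:12)))
    fdv <- as.list(stats::setNames(b$fd, sprintf("fd_%d",
                                                 seq_along(b$fd))))
    as.data.frame(c(list(subject = b$subject, run = b$run, block = b$block,
                         condition = b$condition, hit_rate = b$hit_rate,
                         amplitude_true = b$amplitude_true), smp, fdv),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname fmri_blocks_to_df
#' @param df A data frame produced by `fmri_blocks_to_df()`.
#' @export
df_to_fmri_blocks <- function(df) {
  smp_cols <- sprintf("sample_%d", 1:12)
  fd_cols <- grep("^fd_", names(df), value = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    block_timecourse(
      samples = as.numeric(df[i, smp_cols]),
      fd = as.numeric(df[i, fd_cols]),
      subject = df$subject[i], run = df$run[i], block = df$block[i],
      condition = df$condition[i], hit_rate = df$hit_rate[i],
      amplitude_true = df$amplitude_true[i])
  })
}

#' Load a pipeline configuration from JSON
#'
#' Recognized top-level keys: any argument of [cohort_config()] except
#' `catalogue` and `model`, plus a `model` object holding [model_params()]
#' arguments, and analysis options `alpha`, `split_mode`,
#' `screen_conditions`. Unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return A list with `cohort` ([cohort_config()]) and `analysis` options.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_pipeline_config: no such file: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  analysis_keys <- c("alpha", "split_mode", "screen_conditions")
  cohort_keys <- setdiff(names(formals(cohort_config)),
                         c("catalogue", "model"))
  unknown <- setdiff(names(raw), c(analysis_keys, cohort_keys, "model"))
  if (length(unknown) > 0) {
    stop("read_pipeline_config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  model <- if (!is.null(raw$model)) {
    unknown_m <- setdiff(names(raw$model), names(formals(model_params)))
    if (length(unknown_m) > 0) {
      stop("read_pipeline_config: unknown model key(s): ",
           paste(unknown_m, collapse = ", "), call. = FALSE)
    }
    do.call(model_params, raw$model)
  } else {
    model_params()
  }
  cohort_args <- raw[intersect(names(raw), cohort_keys)]
  cohort_args$model <- model
  analysis <- list(alpha = raw$alpha %||% 0.01,
                   split_mode = raw$split_mode %||% "thirds",
                   screen_conditions = raw$screen_conditions %||%
                     c("small_high", "medium_high"))
  list(cohort = do.call(cohort_config, cohort_args), analysis = analysis)
}

# FNV-1a over a string, reduced mod 2^26-adjacent prime (exact in doubles);
# used only to fingerprint configurations in provenance files.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) h <- (h * 33 + ch) %% 67108859
  sprintf("%08x", h)
}

write_provenance <- function(dir, config, seed, extra = list()) {
  prov <- c(list(
    package = "normgain",
    version = as.character(utils::packageVersion("normgain")),
    seed = seed,
    config_hash = config_hash(strip_config(config)),
    r_version = R.version.string
  ), extra)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prov)
}

strip_config <- function(cfg) {
  cfg$catalogue <- NULL
  unclass(cfg)
}
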