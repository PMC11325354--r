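# Shared test fixtures, built in code.

# trapezoidal quadrature (independent oracle for field integrals)
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# brute-force expected-entropy oracle for the Psi selection rule: plain
# loops over every stimulus and both response branches, no shared code with
# psi_select beyond the likelihood matrix.
brute_force_psi_select <- function(state) {
  n_stim <- length(state$stimulus_grid)
  eh <- numeric(n_stim)
  for (j in seq_len(n_stim)) {
    e <- 0
    for (resp in c(TRUE, FALSE)) {
      lik <- if (resp) state$P[, j] else 1 - state$P[, j]
      joint <- state$posterior * lik
      pr <- sum(joint)
      if (pr > 0) {
        q <- joint / pr
        h <- 0
        for (v in q) if (v > 0) h <- h - v * log(v)
        e <- e + pr * h
      }
    }
    eh[j] <- e
  }
  best <- which(eh <= min(eh) + 1e-12)[1]
  state$stimulus_grid[best]
}

# a synthetic staircase record with a prescribed running-estimate series
record_with_estimates <- function(est) {
  list(trials = data.frame(trial = seq_along(est),
                           stimulus = rep(100, length(est)),
                           correct = 1L, estimate = est),
       threshold_80 = est[length(est)])
}

# minimal parcel table with the designated parcels plus fillers, areas
# chosen by the caller per subject; with `total` set, the filler absorbs the
# remainder so every hemisphere total is identical across subjects (making
# shares proportional to the areas passed in)
tiny_parcel_table <- function(region_sums_parietal, frontal_areas,
                              filler = 1000, total = NULL) {
  subjects <- names(region_sums_parietal)
  rows <- list()
  par <- parietal_region()$members
  for (s in subjects) {
    fill_r <- if (is.null(total)) filler else
      total - region_sums_parietal[[s]]
    fill_l <- if (is.null(total)) filler else total - frontal_areas[[s]]
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, hemisphere = "R",
      parcel = c(par$parcel, "ROI_001"),
      area_mm2 = c(rep(region_sums_parietal[[s]] / 5, 5), fill_r))
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, hemisphere = "L",
      parcel = c("11l", "ROI_001"),
      area_mm2 = c(frontal_areas[[s]], fill_l))
  }
  do.call(rbind, rows)
}

# FreeSurfer mris_anatomical_stats-style fixture
write_fs_stats <- function(path, hemi = "lh", parcels = c("V1", "MT", "11l"),
                           areas = c(2300, 810, 640)) {
  lines <- c(
    "# Table of FreeSurfer cortical parcellation anatomical statistics",
    "#",
    sprintf("# hemi %s", hemi),
    "# anatomy_type surface",
    "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd",
    sprintf("%s  %d  %.1f  %.1f  2.5  0.5  0.1  0.01  10  1.0",
            parcels, seq_along(parcels) * 1000L, areas, areas * 2.5)
  )
  writeLines(lines, path)
  path
}
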