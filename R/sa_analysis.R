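# Cortical surface-area analytics: parcel-share normalization, region sums,
# correlation screening across the atlas, group splits and condition-wise
# correlation summaries.

#' Define a cortical region as a set of parcels
#'
#' @param name Region name.
#' @param hemisphere Hemisphere label(s) (`"L"`/`"R"`), recycled against
#'   `parcels`.
#' @param parcels Parcel names.
#' @return An object of class `region_def`.
#' @export
#' @examples
#' parietal_region()
region_def <- function(name, hemisphere, parcels) {
  if (length(parcels) == 0L) {
    stop("region_def: a region needs at least one parcel", call. = FALSE)
  }
  members <- data.frame(hemisphere = rep_len(hemisphere, length(parcels)),
                        parcel = parcels, stringsAsFactors = FALSE)
  structure(list(name = name, members = members), class = "region_def")
}

#' @export
print.region_def <- function(x, ...) {
  cat(sprintf("<region_def> %s: %s\n", x$name,
              paste(x$members$hemisphere, x$members$parcel, sep = "_",
                    collapse = ", ")))
  invisible(x)
}

#' @rdname region_def
#' @details `parietal_region()` is the cluster of five right-parietal parcels
#'   (7AL, VIP, LIPd, IP1, IP2) whose summed normalized surface area tracks
#'   the spatial extent of excitatory receptive fields; `frontal_region()` is
#'   the left-frontal parcel 11l associated with the width of top-down gain.
#' @export
parietal_region <- function() {
  region_def("parietal", "R", c("7AL", "VIP", "LIPd", "IP1", "IP2"))
}

#' @rdname region_def
#' @export
frontal_region <- function() {
  region_def("frontal", "L", "11l")
}

check_parcel_table <- function(table) {
  need <- c("subject", "hemisphere", "parcel", "area_mm2")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop("parcel table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(table$subject, table$hemisphere, table$parcel)
  if (anyDuplicated(key)) {
    stop("parcel table has duplicated (subject, hemisphere, parcel) rows",
         call. = FALSE)
  }
  if (any(!is.finite(table$area_mm2)) || any(table$area_mm2 <= 0)) {
    stop("parcel areas must be positive and finite", call. = FALSE)
  }
  invisible(table)
}

#' Normalize parcel surface areas to hemispheric shares
#'
#' Each parcel's surface area is expressed as a percentage of the summed
#' parcel area of its hemisphere within the subject:
#' `share = area / hemisphere_total * 100`. Raw areas are retained, so the
#' operation is idempotent and invariant to overall brain size.
#'
#' @param table A parcel table: data frame with columns `subject`,
#'   `hemisphere`, `parcel`, `area_mm2`.
#' @return The table with a `normalized` column (percent).
#' @export
normalize_sa <- function(table) {
  check_parcel_table(table)
  key <- paste(table$subject, table$hemisphere)
  totals <- tapply(table$area_mm2, key, sum)
  if (any(totals <= 0)) {
    bad <- unique(sub(" .*$", "", names(totals)[totals <= 0]))
    stop("normalize_sa: zero hemisphere total for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  table$normalized <- table$area_mm2 / as.numeric(totals[key]) * 100
  table
}

#' Per-subject summed normalized surface area of a region
#'
#' @param table A normalized parcel table (see [normalize_sa()]).
#' @param region A [region_def()].
#' @return A named numeric vector of summed shares, one per subject.
#' @export
region_sum <- function(table, region) {
  if (is.null(table$normalized)) table <- normalize_sa(table)
  subjects <- unique(table$subject)
  out <- numeric(length(subjects))
  names(out) <- subjects
  for (k in seq_len(nrow(region$members))) {
    hemi <- region$members$hemisphere[k]
    pc <- region$members$parcel[k]
    rows <- table[table$hemisphere == hemi & table$parcel == pc, ]
    if (!all(subjects %in% rows$subject)) {
      missing_s <- setdiff(subjects, rows$subject)
      stop(sprintf("region_sum: parcel %s_%s missing for subject(s): %s",
                   hemi, pc, paste(missing_s, collapse = ", ")),
           call. = FALSE)
    }
    out[rows$subject] <- out[rows$subject] + rows$normalized
  }
  out
}

#' Pearson correlation with the t-transform p-value
#'
#' Sample Pearson correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, the
#' reporting convention used throughout the analyses.
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values are
#'   dropped.
#' @return A list with `r`, `p`, `df` and `n`.
#' @export
#' @examples
#' pearson_r(1:4, c(1, 3, 2, 4))$r
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("pearson_r: need at least 3 complete pairs", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop("pearson_r: undefined correlation (zero variance)", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  list(r = r, p = p, df = df, n = n)
}

#' Screen all parcels for correlation with a behavioral measure
#'
#' Correlates every parcel's normalized share with a per-subject behavioral
#' scalar and returns the parcels passing `p < alpha`, keeping the sign of
#' the correlation. No multiplicity correction is applied by default,
#' matching the uncorrected screening threshold of the original analysis;
#' Benjamini-Hochberg adjustment is available via `adjust`.
#'
#' @param parcels A parcel table (normalized if needed).
#' @param behavior Named numeric vector of per-subject values (names =
#'   subject IDs), or a data frame with `subject` and `value` columns.
#'   Subjects with missing behavior are dropped pairwise.
#' @param alpha Significance threshold (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param return_all If `TRUE`, return every parcel with a `pass` column
#'   instead of only the passing set.
#' @return A data frame with `hemisphere`, `parcel`, `r`, `p`, `n` (and
#'   `pass` when `return_all`), ordered by p-value.
#' @export
screen_parcels <- function(parcels, behavior, alpha = 0.01,
                           adjust = c("none", "BH"), return_all = FALSE) {
  adjust <- match.arg(adjust)
  if (is.data.frame(behavior)) {
    behavior <- stats::setNames(behavior$value, behavior$subject)
  }
  if (is.null(parcels$normalized)) parcels <- normalize_sa(parcels)
  b <- behavior[is.finite(behavior)]
  keep <- parcels$subject %in% names(b)
  if (length(unique(parcels$subject[keep])) < 10) {
    stop("screen_parcels: need >= 10 subjects with both measures",
         call. = FALSE)
  }
  sub <- parcels[keep, ]
  key <- paste(sub$hemisphere, sub$parcel, sep = "\r")
  wide <- tapply(sub$normalized, list(sub$subject, key), sum)
  bv <- as.numeric(b[rownames(wide)])
  # vectorized per-parcel Pearson r against the behavioral scalar
  # (pairwise deletion already applied: only subjects with behavior remain)
  n <- nrow(wide)
  xc <- sweep(wide, 2, colMeans(wide))
  sx <- sqrt(colSums(xc^2))
  yc <- bv - mean(bv)
  sy <- sqrt(sum(yc^2))
  const <- sx <= 1e-10 * pmax(abs(colMeans(wide)), .Machine$double.xmin)
  r <- as.numeric(crossprod(xc, yc)) / ifelse(const, NA_real_, sx * sy)
  if (any(const)) {
    warning("screen_parcels: skipping constant parcel(s): ",
            paste(gsub("\r", "_", colnames(wide)[const]), collapse = ", "),
            call. = FALSE)
  }
  r <- pmin(1, pmax(-1, r))
  df <- n - 2L
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tval), df))
  hemi_parcel <- do.call(rbind, strsplit(colnames(wide), "\r", fixed = TRUE))
  out <- data.frame(hemisphere = hemi_parcel[, 1], parcel = hemi_parcel[, 2],
                    r = r, p = p, n = n, stringsAsFactors = FALSE)
  out <- out[!const, ]
  p_eff <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$pass <- p_eff < alpha
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  if (return_all) out else out[out$pass, setdiff(names(out), "pass")]
}

#' Split subjects into extreme groups
#'
#' `"thirds"` labels the bottom and top `floor(n/3)` subjects (by value)
#' `"low"` and `"high"`, leaving the middle unlabeled (`NA`) — the split used
#' for the main cohort. `"halves"` labels the bottom `ceiling(n/2)` and top
#' `floor(n/2)` — used for the smaller spatial-integration cohort. Ties break
#' by subject-ID order, so the split is deterministic.
#'
#' @param values Named numeric vector (names = subject IDs).
#' @param mode `"thirds"` or `"halves"`.
#' @return A named character vector of labels (`"low"`, `"high"`, or `NA`).
#' @export
group_split <- function(values, mode = c("thirds", "halves")) {
  mode <- match.arg(mode)
  if (any(!is.finite(values))) {
    stop("group_split: values must be finite", call. = FALSE)
  }
  n <- length(values)
  if (n < if (mode == "thirds") 3 else 2) {
    stop("group_split: too few subjects", call. = FALSE)
  }
  ord <- order(values, names(values))
  lab <- rep(NA_character_, n)
  if (mode == "thirds") {
    k <- n %/% 3
    lab[ord[seq_len(k)]] <- "low"
    lab[ord[(n - k + 1):n]] <- "high"
  } else {
    k <- (n + 1L) %/% 2L
    lab[ord[seq_len(k)]] <- "low"
    lab[ord[(k + 1):n]] <- "high"
  }
  names(lab) <- names(values)
  lab
}

#' Per-subject behavioral summary over named conditions
#'
#' Averages thresholds over the conditions named in the recipe (e.g. the two
#' smallest high-contrast conditions, or the Exp-2 small- and large-gap
#' averages). A subject missing any named condition gets `NA`, which
#' propagates pairwise into downstream correlations.
#'
#' @param table A threshold table: data frame with `subject`, `condition`,
#'   `threshold`.
#' @param conditions Character vector of condition labels to average.
#' @return Named numeric vector of per-subject means.
#' @export
behavioral_summary <- function(table, conditions) {
  unknown <- setdiff(conditions, unique(table$condition))
  if (length(unknown) > 0) {
    stop("behavioral_summary: unknown condition(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  subjects <- unique(table$subject)
  out <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
  sub <- table[table$condition %in% conditions, ]
  for (s in subjects) {
    v <- sub$threshold[sub$subject == s]
    if (length(v) == length(conditions) && all(is.finite(v))) {
      out[s] <- mean(v)
    }
  }
  out
}

#' Region-by-condition correlation table
#'
#' Correlates each region's summed normalized surface area with thresholds in
#' each named condition, reporting the pairwise n per cell.
#'
#' @param regions A list of [region_def()] objects.
#' @param conditions Character vector of condition labels.
#' @param parcels A parcel table.
#' @param thresholds A threshold table (`subject`, `condition`, `threshold`).
#' @return A data frame with `region`, `condition`, `r`, `p`, `n`.
#' @export
condition_correlation_matrix <- function(regions, conditions, parcels,
                                         thresholds) {
  if (is.null(parcels$normalized)) parcels <- normalize_sa(parcels)
  rows <- list()
  for (reg in regions) {
    sa <- region_sum(parcels, reg)
    for (cond in conditions) {
      thr <- behavioral_summary(thresholds, cond)
      common <- intersect(names(sa), names(thr))
      ct <- pearson_r(sa[common], thr[common])
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg$name, condition = cond, r = ct$r, p = ct$p, n = ct$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
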