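test_that("surface-area normalization follows the hemispheric-share formula", {
  tab <- data.frame(subject = "S1", hemisphere = "R",
                    parcel = c("A", "B", "C"),
                    area_mm2 = c(300, 89000, 700))
  norm <- normalize_sa(tab)
  expect_equal(norm$normalized[1], 300 / 90000 * 100)
  expect_equal(norm$normalized[1], 0.3333, tolerance = 1e-3)
  expect_equal(sum(norm$normalized), 100, tolerance = 1e-9)

  # scale invariance and idempotence
  tab2 <- tab; tab2$area_mm2 <- tab$area_mm2 * 2
  expect_equal(normalize_sa(tab2)$normalized, norm$normalized)
  expect_equal(normalize_sa(norm)$normalized, norm$normalized)

  dup <- rbind(tab, tab[1, ])
  expect_error(normalize_sa(dup), "duplicated")
  bad <- tab; bad$area_mm2[1] <- -5
  expect_error(normalize_sa(bad), "positive")
})

test_that("region sums add member shares and reject missing members", {
  sums <- c(S1 = 6000, S2 = 5000)
  tab <- tiny_parcel_table(sums, c(S1 = 700, S2 = 650))
  norm <- normalize_sa(tab)
  rs <- region_sum(norm, parietal_region())
  manual <- vapply(c("S1", "S2"), function(s) {
    sub <- norm[norm$subject == s & norm$hemisphere == "R" &
                  norm$parcel != "ROI_001", ]
    sum(sub$normalized)
  }, numeric(1))
  expect_equal(rs, manual)
  # single-parcel region is the identity on that parcel's share
  fr <- region_sum(norm, frontal_region())
  expect_equal(unname(fr["S1"]),
               norm$normalized[norm$subject == "S1" &
                                 norm$parcel == "11l"])
  # permutation of members changes nothing
  perm <- region_def("parietal", "R", rev(parietal_region()$members$parcel))
  expect_equal(region_sum(norm, perm), rs)
  expect_error(region_sum(norm, region_def("x", "L", "nope")), "missing")
})

test_that("pearson_r matches the definitional brute force and cor.test", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(1:4, c(1, 3, 2, 4))$r, 0.8)
  set.seed(99)
  for (k in 1:1000) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_r(x, y)
    # brute force from the definition
    r_bf <- mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
    expect_equal(got$r, r_bf, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(got$p, unname(ct$p.value), tolerance = 1e-12)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("screening keeps sign, nests across alpha, and skips constant parcels", {
  set.seed(123)
  n <- 40
  subjects <- sprintf("S%02d", 1:n)
  behavior <- setNames(rnorm(n, 100, 20), subjects)
  mk <- function(parcel, shares) data.frame(subject = subjects,
                                            hemisphere = "R",
                                            parcel = parcel,
                                            area_mm2 = shares)
  planted <- 1000 - 3 * (behavior - 100) + rnorm(n, 0, 10)
  noiseA <- rnorm(n, 1000, 40)
  noiseB <- rnorm(n, 800, 30)
  flat <- rep(500, n)
  bulk <- 100000 - planted - noiseA - noiseB - flat  # equal totals, so the
  tab <- rbind(mk("planted", planted), mk("noiseA", noiseA),
               mk("noiseB", noiseB), mk("flat", flat),
               mk("bulk", bulk))                     # flat share is constant
  expect_warning(scr <- screen_parcels(tab, behavior, alpha = 0.05,
                                       return_all = TRUE), "constant")
  expect_false("flat" %in% scr$parcel)
  expect_true(scr$pass[scr$parcel == "planted"])
  expect_lt(scr$r[scr$parcel == "planted"], 0)
  suppressWarnings({
    hits1 <- screen_parcels(tab, behavior, alpha = 0.01)
    hits5 <- screen_parcels(tab, behavior, alpha = 0.05)
    hits0 <- screen_parcels(tab, behavior, alpha = 0)
  })
  expect_true(all(paste(hits1$hemisphere, hits1$parcel) %in%
                    paste(hits5$hemisphere, hits5$parcel)))
  expect_equal(nrow(hits0), 0L)
})

test_that("planted screening recovers the target parcel across replicates", {
  hits <- vapply(1:20, function(rep) {
    set.seed(1000 + rep)
    n <- 62
    subjects <- sprintf("S%02d", 1:n)
    behavior <- setNames(rlnorm(n, log(40), 0.3), subjects)
    tab <- do.call(rbind, lapply(sprintf("P%02d", 1:20), function(pc) {
      data.frame(subject = subjects, hemisphere = "L", parcel = pc,
                 area_mm2 = rlnorm(n, log(500), 0.1))
    }))
    planted <- tab$parcel == "P01"
    tab$area_mm2[planted] <- 500 * exp(-0.8 * scale(log(behavior))[, 1] +
                                         rnorm(n, 0, 0.05))
    scr <- screen_parcels(tab, behavior, alpha = 0.01)
    "P01" %in% scr$parcel && scr$r[scr$parcel == "P01"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("group splits partition deterministically with stated sizes", {
  v62 <- setNames(seq_len(62), sprintf("S%03d", 1:62))
  g <- group_split(v62, "thirds")
  expect_equal(sum(g == "low", na.rm = TRUE), 20)
  expect_equal(sum(g == "high", na.rm = TRUE), 20)
  expect_equal(sum(is.na(g)), 22)
  expect_true(all(v62[which(g == "low")] < v62[which(g == "high")]))

  v29 <- setNames(rnorm(29), sprintf("S%03d", 1:29))
  h <- group_split(v29, "halves")
  expect_equal(as.integer(table(h)[c("low", "high")]), c(15L, 14L))
  expect_equal(sum(is.na(h)), 0)

  ties <- setNames(rep(1, 4), c("b", "a", "d", "c"))
  t1 <- group_split(ties, "halves")
  expect_equal(t1[["a"]], "low")   # tie-break by subject ID
  expect_equal(t1[["d"]], "high")
  expect_error(group_split(c(a = 1, b = NA), "halves"), "finite")
})

test_that("behavioral summaries average named conditions and propagate missingness", {
  tab <- data.frame(
    subject = rep(c("S1", "S2"), each = 3),
    condition = rep(c("small_high", "medium_high", "large_high"), 2),
    threshold = c(30, 40, 60, 55, 50, 60))
  out <- behavioral_summary(tab, c("small_high", "medium_high"))
  expect_equal(unname(out["S1"]), 35)
  expect_equal(unname(out["S2"]), 52.5)
  expect_equal(unname(behavioral_summary(
    tab, c("small_high", "medium_high", "large_high"))["S2"]), 55)
  # S2 missing one named condition -> NA
  tab2 <- tab[-4, ]
  out2 <- behavioral_summary(tab2, c("small_high", "medium_high"))
  expect_true(is.na(out2["S2"]))
  expect_false(is.na(out2["S1"]))
  expect_error(behavioral_summary(tab, "nope"), "unknown")
})

test_that("condition correlation matrix covers the region-by-condition grid", {
  set.seed(5)
  sums <- setNames(rnorm(20, 6000, 500), sprintf("S%02d", 1:20))
  fro <- setNames(rnorm(20, 650, 60), names(sums))
  tab <- normalize_sa(tiny_parcel_table(as.list(sums), as.list(fro)))
  thr <- do.call(rbind, lapply(names(sums), function(s) {
    data.frame(subject = s, condition = c("small_low", "large_low"),
               threshold = rlnorm(2, log(60), 0.2))
  }))
  cm <- condition_correlation_matrix(
    list(parietal_region(), frontal_region()),
    c("small_low", "large_low"), tab, thr)
  expect_equal(nrow(cm), 4L)
  expect_equal(cm$n, rep(20L, 4))
  cm2 <- condition_correlation_matrix(
    list(parietal_region(), parietal_region()),
    "small_low", tab, thr)
  expect_equal(cm2$r[1], cm2$r[2])
})
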