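test_that("cohort generation is deterministic given config and seed", {
  cfg <- cohort_config(n_subjects = 6, experiments = c("exp1", "fmri"),
                       seed = 42)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1$parcels, d2$parcels)
  expect_identical(d1$thresholds_exp1, d2$thresholds_exp1)
  expect_identical(fmri_blocks_to_df(d1$fmri), fmri_blocks_to_df(d2$fmri))
  d3 <- generate_cohort(cohort_config(n_subjects = 6,
                                      experiments = "exp1", seed = 43))
  expect_false(identical(d1$thresholds_exp1$threshold,
                         d3$thresholds_exp1$threshold))
})

test_that("sampled parcel tables have full catalogues and plausible shares", {
  cfg <- cohort_config(n_subjects = 12, seed = 3)
  tab <- normalize_sa(sample_parcel_table(cfg))
  expect_equal(nrow(tab), 12 * 360)
  sums <- tapply(tab$normalized, paste(tab$subject, tab$hemisphere), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # the stated share range: most parcels between 0.2% and 2%
  expect_gt(mean(tab$normalized > 0.2 & tab$normalized < 2), 0.95)
})

test_that("parietal and frontal shares are uncorrelated by construction", {
  cfg <- cohort_config(n_subjects = 1000, seed = 8)
  tab <- normalize_sa(sample_parcel_table(cfg))
  par_sa <- region_sum(tab, parietal_region())
  fro_sa <- region_sum(tab, frontal_region())
  r <- pearson_r(par_sa, fro_sa)$r
  expect_gt(r, -0.1)
  expect_lt(r, 0.1)
  # and the cluster is internally correlated
  p1 <- tab$normalized[tab$parcel == "7AL"]
  p2 <- tab$normalized[tab$parcel == "VIP"]
  expect_gt(pearson_r(p1, p2)$r, 0.3)
})

test_that("surface area maps onto model widths monotonically with clipping", {
  # construct region sums with one extreme subject
  sums <- c(S1 = 5000, S2 = 5200, S3 = 5400, S4 = 5600, S5 = 20000)
  fro <- c(S1 = 600, S2 = 620, S3 = 640, S4 = 660, S5 = 680)
  tab <- tiny_parcel_table(sums, fro, filler = 80000)
  cfg <- cohort_config(n_subjects = 5, seed = 1)
  mp <- map_sa_to_params(tab, cfg)
  # ranks of w_E reverse the ranks of parietal share (before ties from clip)
  expect_equal(order(mp$w_E), rev(order(mp$z_parietal)))
  expect_equal(mp$w_E[mp$subject == "S5"], 3)   # clipped at the narrow bound
  # a subject at the cohort mean sits at the midpoint (equal hemisphere
  # totals make shares proportional to the constructed sums)
  mid <- tiny_parcel_table(c(A = 5000, B = 6000, C = 7000),
                           c(A = 600, B = 650, C = 700), total = 90000)
  mpm <- map_sa_to_params(mid, cfg)
  expect_equal(mpm$w_E[mpm$subject == "B"], 3.75, tolerance = 1e-6)
  expect_equal(mpm$w_A[mpm$subject == "B"], 5, tolerance = 1e-6)
  expect_error(map_sa_to_params(tab[tab$parcel != "11l", ], cfg), "missing")
})

test_that("fast-fidelity sessions reduce to model predictions at zero noise", {
  cfg <- cohort_config(n_subjects = 3, seed = 2, threshold_noise_sdlog = 0)
  params <- model_params()
  ses <- simulate_observer_session(params, conditions_exp1(), cfg, seed = 9)
  expect_equal(ses$threshold, ses$truth)
  expect_equal(ses$threshold[ses$condition == "small_high"],
               predict_threshold(grating_stimulus(0.5, 0.98), params))
  expect_equal(ses$threshold[ses$condition == "large_low"],
               predict_threshold(grating_stimulus(6, 0.03), params))
})

test_that("full-fidelity sessions are reproducible and track the fast truth", {
  cfg <- cohort_config(n_subjects = 3, seed = 21, fidelity = "full")
  params <- model_params()
  cond <- conditions_exp1()[c(4, 5), ]   # two high-contrast conditions
  s1 <- simulate_observer_session(params, cond, cfg, seed = 77)
  s2 <- simulate_observer_session(params, cond, cfg, seed = 77)
  expect_identical(s1, s2)
  expect_true(all(abs(s1$threshold / s1$truth - 1) < 0.35))
})

test_that("full and fast fidelities agree for most condition cells", {
  cfg <- cohort_config(n_subjects = 6, experiments = "exp1",
                       fidelity = "full", seed = 11)
  ds <- generate_cohort(cfg)
  t1 <- ds$thresholds_exp1
  within20 <- abs(t1$threshold / t1$truth - 1) < 0.2
  expect_gte(mean(within20), 0.8)
  expect_true(all(t1$threshold > 0))
})

test_that("exp-2 and exp-5 tables cover their designs", {
  cfg <- cohort_config(n_subjects = 4, seed = 13,
                       experiments = c("exp2", "exp5"))
  ds <- generate_cohort(cfg)
  expect_equal(nrow(ds$thresholds_exp2), 4 * 6)
  expect_setequal(unique(ds$thresholds_exp2$condition),
                  conditions_exp2()$label)
  # gap thresholds fall toward the isolated-target threshold
  m <- tapply(ds$thresholds_exp2$truth, ds$thresholds_exp2$condition, mean)
  expect_lt(m[["gap_4.5"]], m[["gap_0.5"]])
  expect_equal(nrow(ds$thresholds_exp5), 4L)
  expect_true(all(ds$thresholds_exp5$threshold < 1))
})

test_that("synthetic fMRI blocks carry the planted amplitude exactly when noise-free", {
  cfg <- cohort_config(n_subjects = 3, seed = 5, experiments = "fmri",
                       fmri_noise_sd = 0, fd_spike_prob = 0)
  ds <- generate_cohort(cfg)
  expect_equal(length(ds$fmri), 3 * 2 * 2 * 6)
  for (b in ds$fmri[c(1, 30, 60)]) {
    psc <- percent_signal_change(b)
    expect_equal(response_magnitude(psc), b$amplitude_true, tolerance = 1e-12)
    expect_equal(mean(psc[1:3]), 0, tolerance = 1e-12)
  }
  resp <- condition_response(ds$fmri)
  truth <- vapply(seq_len(nrow(resp)), function(i) {
    amps <- vapply(ds$fmri, function(b) {
      if (b$subject == resp$subject[i] && b$condition == resp$condition[i])
        b$amplitude_true else NA_real_
    }, numeric(1))
    mean(amps, na.rm = TRUE)
  }, numeric(1))
  expect_equal(resp$response, truth, tolerance = 1e-12)
  # high contrast drives a bigger response than low
  hi <- resp$response[resp$condition == "high"]
  lo <- resp$response[resp$condition == "low"]
  expect_true(all(hi > lo))
})
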