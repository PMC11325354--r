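make_block <- function(samples = rep(100, 12), fd = rep(0.1, 15), ...) {
  block_timecourse(samples = samples, fd = fd, ...)
}

test_that("percent signal change is anchored to the pre-onset baseline", {
  expect_equal(percent_signal_change(make_block()), rep(0, 12))
  b <- make_block(samples = c(100, 100, 100, rep(102, 9)))
  psc <- percent_signal_change(b)
  expect_equal(psc[4], 2)
  expect_equal(mean(psc[1:3]), 0)
  # invariant to a positive rescaling of the raw samples
  b2 <- make_block(samples = b$samples * 7.3)
  expect_equal(percent_signal_change(b2), psc, tolerance = 1e-12)
  expect_error(percent_signal_change(make_block(samples = c(-1, -1, -1,
                                                            rep(1, 9)))),
               "baseline")
})

test_that("response magnitude averages the 8-12 s window only", {
  psc <- rep(0, 12)
  psc[seq(-4, 18, 2) %in% c(8, 10, 12)] <- c(1, 2, 3)
  expect_equal(response_magnitude(psc), 2)
  expect_equal(response_magnitude(rep(0, 12)), 0)
  psc[seq(-4, 18, 2) == 14] <- 50   # outside the window
  expect_equal(response_magnitude(psc), 2)
})

test_that("block exclusion follows the framewise-displacement window rule", {
  fd <- rep(0.1, 15)
  fd[-8:6 == -3] <- 1.0
  expect_true(exclude_block(make_block(fd = fd)))
  expect_false(exclude_block(make_block(fd = rep(0.5, 15))))
  # a spike one TR before the window does not count
  fd2 <- c(2.0, rep(0.1, 15))
  b <- block_timecourse(rep(100, 12), fd = fd2, fd_times = -9:6)
  expect_false(exclude_block(b))
  short <- block_timecourse(rep(100, 12), fd = rep(0.1, 10),
                            fd_times = -8:1)
  expect_error(exclude_block(short), "window")
  expect_error(block_timecourse(rep(100, 12), fd = rep(-1, 15)), "FD")
  expect_error(block_timecourse(rep(100, 11), fd = rep(0.1, 15)),
               "12 finite samples")
})

test_that("run exclusion needs a majority of bad blocks or a low hit rate", {
  mk_run <- function(n_bad_low, hit = 0.9) {
    blocks <- list()
    for (cond in c("low", "high")) {
      for (i in 1:6) {
        bad <- cond == "low" && i <= n_bad_low
        fd <- rep(if (bad) 1.2 else 0.1, 15)
        blocks[[length(blocks) + 1L]] <-
          make_block(fd = fd, condition = cond, hit_rate = hit)
      }
    }
    blocks
  }
  expect_true(exclude_run(mk_run(4)))
  expect_false(exclude_run(mk_run(3)))          # exactly half is retained
  expect_true(exclude_run(mk_run(0, hit = 0.55)))
  expect_false(exclude_run(mk_run(0, hit = 0.60)))
  expect_error(exclude_run(list()), "no blocks")
})

test_that("condition responses average retained blocks and mark empty cells", {
  b1 <- make_block(samples = c(rep(100, 3), rep(102, 9)),
                   subject = "S1", condition = "high")
  expect_equal(condition_response(list(b1))$response,
               response_magnitude(percent_signal_change(b1)))
  expect_equal(condition_response(list(b1, b1))$response,
               response_magnitude(percent_signal_change(b1)))
  bad <- make_block(samples = c(rep(100, 3), rep(104, 9)),
                    fd = rep(1.5, 15), subject = "S1", condition = "high",
                    block = 2)
  cr <- condition_response(list(b1, b1, bad))
  expect_equal(cr$n_blocks, 2L)   # the spiky block is dropped
  expect_equal(cr$response, 2)
  # a run below the hit-rate floor contributes nothing
  lowhit <- make_block(subject = "S2", condition = "high", hit_rate = 0.5)
  cr2 <- condition_response(list(b1, lowhit))
  expect_true(is.na(cr2$response[cr2$subject == "S2"]))
})

test_that("frontal surface area tracks hMT+ responsiveness in planted cohorts", {
  res <- vapply(1:10, function(s) {
    cfg <- cohort_config(n_subjects = 30, seed = 400 + s,
                         experiments = "fmri")
    ds <- generate_cohort(cfg)
    cr <- condition_response(ds$fmri)
    hi <- setNames(cr$response[cr$condition == "high"],
                   cr$subject[cr$condition == "high"])
    parcels <- normalize_sa(ds$parcels)
    fro <- region_sum(parcels, frontal_region())[names(hi)]
    par <- region_sum(parcels, parietal_region())[names(hi)]
    rf <- pearson_r(fro, hi)$r
    rp <- pearson_r(par, hi)$r
    rf > 0 && rf > rp
  }, logical(1))
  expect_gte(mean(res), 0.8)
})
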