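test_that("stimulus drive: zero input, symmetry, unit-area kernel preserves integral", {
  p <- model_params()

  zero <- stimulus_drive(grating_stimulus(1.5, 0), p)
  expect_true(all(zero$E == 0))

  drv <- stimulus_drive(grating_stimulus(1.5, 0.5), p)
  expect_equal(drv$E, rev(drv$E), tolerance = 1e-10)
  expect_equal(drv$x[which.max(drv$E)], 0)
  expect_true(all(drv$E >= 0))

  # integral of the convolved drive equals contrast x support width, against
  # trapezoidal quadrature of the un-convolved boxcar
  for (sz in c(0.5, 1.5, 6)) {
    spec <- grating_stimulus(sz, 0.98)
    drv <- stimulus_drive(spec, p)
    want <- 0.98 * sz * p$units_per_degree  # diameter in model units
    got <- trapz(drv$x, drv$E)
    expect_lt(abs(got - want) / want, 0.001)
  }

  # annulus support: two mirrored bands
  spec <- annulus_stimulus(1, contrast = 0.5)
  drv <- stimulus_drive(spec, p)
  band <- (7.75 - 1.25) + 0.25  # surround band + target radius, degrees
  want <- 0.5 * 2 * band * p$units_per_degree
  expect_lt(abs(trapz(drv$x, drv$E) - want) / want, 0.001)
})

test_that("stimulus drive rejects bad specs", {
  p <- model_params(grid_extent = 20)
  expect_error(stimulus_drive(grating_stimulus(6, 0.5), p), "component 1")
  expect_error(stimulus_spec(), "at least one component")
  expect_error(stim_component(outer_deg = 1, contrast = 1.2), "contrast")
  expect_error(stim_component(outer_deg = 0.2, inner_deg = 0.5,
                              contrast = 0.5), "outer radius")
  expect_error(
    stimulus_spec(stim_component(0.5, contrast = 0.9),
                  stim_component(0.7, inner_deg = 0.3, contrast = 0.9)),
    "overlap")
  expect_error(model_params(w_S = 2), "broader")
})

test_that("attention field: baseline, peak and symmetry", {
  p0 <- model_params(g_A = 0)
  spec <- grating_stimulus(0.5, 0.98)
  expect_true(all(attention_field(spec, p0)$A == 1))

  p <- model_params(g_A = 2)
  att <- attention_field(spec, p)
  expect_equal(max(att$A), 1 + p$g_A)
  expect_equal(att$x[which.max(att$A)], 0)
  expect_equal(att$A, rev(att$A))
  expect_true(all(att$A >= 1))
})

test_that("population response identity, positivity and algebraic bound", {
  p <- model_params()
  for (spec in list(grating_stimulus(0.5, 0.03), grating_stimulus(6, 0.98),
                    annulus_stimulus(1.5))) {
    r <- population_response(spec, p)
    expect_equal(r$R, r$E_att / (r$S + p$sigma))
    expect_true(all(r$R >= 0))
    expect_true(all(r$R <= r$E_att / p$sigma + 1e-12))
    expect_equal(r$peak, max(r$R))
    # centered stimuli give mirror-symmetric response fields
    expect_equal(r$R, rev(r$R), tolerance = 1e-9)
  }
  # for single gratings the response peaks at the stimulus center
  for (spec in list(grating_stimulus(0.5, 0.03), grating_stimulus(6, 0.98))) {
    r <- population_response(spec, p)
    expect_lt(abs(r$x[which.max(r$R)]), p$grid_step)
  }
  z <- population_response(grating_stimulus(1.5, 0), p)
  expect_true(all(z$R == 0))
  expect_identical(z$peak, 0)
  expect_error(predict_threshold(grating_stimulus(1.5, 0), p), "undefined")
})

test_that("peak response is strictly increasing in contrast", {
  p <- model_params()
  for (sz in c(0.5, 6)) {
    peaks <- vapply(seq(0.01, 0.98, length.out = 20), function(ct)
      population_response(grating_stimulus(sz, ct), p)$peak, numeric(1))
    expect_true(all(diff(peaks) > 0))
  }
})

test_that("contrast response saturates where suppression dominates, not where sigma dominates", {
  p <- model_params()
  pk <- function(sz, ct) population_response(grating_stimulus(sz, ct), p)$peak
  # large stimulus, high contrast: suppression-dominated, near-saturated
  expect_lt(pk(6, 0.98) / pk(6, 0.49) - 1, 0.20)
  # small stimulus, low contrast: sigma-dominated, near-linear
  expect_gt(pk(0.5, 0.03) / pk(0.5, 0.015) - 1, 0.60)
})

test_that("predicted thresholds are k_scale over peak and linear in k_scale", {
  p <- model_params()
  spec <- grating_stimulus(1.5, 0.98)
  r <- population_response(spec, p)
  expect_equal(predict_threshold(spec, p), p$k_scale / r$peak)
  p2 <- p; p2$k_scale <- 2 * p$k_scale
  expect_equal(predict_threshold(spec, p2), 2 * predict_threshold(spec, p))
})

test_that("narrower top-down gain lowers the large low-contrast threshold", {
  narrow <- model_params(); narrow$w_A <- 3
  wide <- model_params(); wide$w_A <- 7
  spec <- grating_stimulus(6, 0.03)
  expect_lt(predict_threshold(spec, narrow), predict_threshold(spec, wide))
})

test_that("condition grid reproduces the size-contrast threshold pattern", {
  g <- predict_condition_grid(params = model_params())
  expect_equal(nrow(g), 6L)
  thr <- function(sz, ct) g$threshold_ms[g$size_deg == sz & g$contrast == ct]
  # high contrast: surround suppression makes larger stimuli harder
  expect_lt(thr(0.5, 0.98), thr(1.5, 0.98))
  expect_lt(thr(1.5, 0.98), thr(6, 0.98))
  # low contrast: spatial summation makes the mid size easier than the small
  expect_lt(thr(1.5, 0.03), thr(0.5, 0.03))
  expect_error(predict_condition_grid(sizes = numeric(0)), "non-empty")
  expect_error(predict_condition_grid(sizes = -1), "invalid size")
})

test_that("parameter_contrast: identity gives zero differences with a warning", {
  p <- model_params()
  expect_warning(pc <- parameter_contrast(p, p), "identical")
  expect_true(all(pc$diff == 0))
})

test_that("narrower excitatory drive acts on small but not large stimuli", {
  narrow <- model_params(); narrow$w_E <- 3
  wide <- model_params(); wide$w_E <- 4.5
  pc <- parameter_contrast(narrow, wide)
  rel <- abs(pc$diff) / pc$threshold_b
  rel_small <- rel[pc$size_deg == 0.5 & pc$contrast == 0.03]
  rel_large <- rel[pc$size_deg == 6 & pc$contrast == 0.03]
  expect_gte(rel_small / rel_large, 3)
  # direction: narrow drive lowers the small-stimulus threshold
  expect_lt(pc$threshold_a[pc$size_deg == 0.5 & pc$contrast == 0.03],
            pc$threshold_b[pc$size_deg == 0.5 & pc$contrast == 0.03])
})

test_that("suppressive pooling width shifts thresholds without reordering conditions", {
  base <- model_params()
  lo <- model_params(w_S = base$w_S * 0.75)
  hi <- model_params(w_S = base$w_S * 1.25)
  g_lo <- predict_condition_grid(params = lo)
  g_hi <- predict_condition_grid(params = hi)
  expect_equal(cor(rank(g_lo$threshold_ms), rank(g_hi$threshold_ms),
                   method = "spearman"), 1)
})

test_that("predictions are stable under grid refinement", {
  g1 <- predict_condition_grid(params = model_params())
  g2 <- predict_condition_grid(params = model_params(grid_step = 0.025))
  expect_true(all(abs(g2$threshold_ms / g1$threshold_ms - 1) < 0.005))
})
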