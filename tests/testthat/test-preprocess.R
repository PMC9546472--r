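test_that("moving average truncates at the edges and preserves constants", {
  expect_equal(moving_average(rep(7, 20), 5, 1), rep(7, 20))
  out <- moving_average(c(1, 2, 3, 4, 5), 5, 1)
  expect_equal(out[3], 3)      # full centered window
  expect_equal(out[1], 2)      # truncated window: mean(1, 2, 3)
  expect_equal(out[5], 4)
  expect_length(out, 5)
  expect_error(moving_average(numeric(0), 5, 1), "empty")
})

test_that("symmetric smoothing does not shift the peak of a cosine", {
  t <- 0:167
  y <- cos(2 * pi * (t - 50) / 24)
  sm <- moving_average(y, 5, 1)
  # one interior cycle holds a unique peak (t = 74); it must not move
  one_cycle <- which(t >= 63 & t <= 86)
  expect_equal(t[one_cycle][which.max(sm[one_cycle])],
               t[one_cycle][which.max(y[one_cycle])])
})

test_that("BAMP detrending removes trends and normalizes the envelope", {
  t <- 0:167
  # pure ramp: baseline absorbs it, interior output ~ 0
  ramp <- 3 + 0.7 * t
  out <- bamp_detrend(ramp, detrend_config(), 1)
  expect_lt(max(abs(out[13:155])), 1e-6)

  # offset cosine: unit-scale cosine out, highly correlated with the source
  y <- 50 + 5 * cos(2 * pi * t / 24)
  out2 <- bamp_detrend(y, detrend_config(), 1)
  expect_gt(cor(out2[13:155], cos(2 * pi * t / 24)[13:155]), 0.99)

  # a linear ramp injected into a rhythmic signal leaves no trace: the
  # detrended output is the same with and without it
  set.seed(4)
  z0 <- 10 + 4 * 2^(-t / 60) * cos(2 * pi * t / 25) + rnorm(168)
  out_no_ramp <- bamp_detrend(z0, detrend_config(), 1)
  out_ramp <- bamp_detrend(z0 + 0.5 * t, detrend_config(), 1)
  # interior = beyond one baseline window, where neither the baseline nor
  # the envelope sees the series ends
  expect_lt(max(abs(out_ramp[25:144] - out_no_ramp[25:144])), 1e-6)
})

test_that("constant input yields zeros with a degenerate-input warning", {
  expect_warning(out <- bamp_detrend(rep(2, 100), detrend_config(), 1),
                 "constant")
  expect_equal(out, rep(0, 100))
})

test_that("mean normalization supports ratio and centered modes", {
  r <- normalize_to_mean(c(2, 4, 6), "ratio")
  expect_equal(as.numeric(r), c(0.5, 1, 1.5))
  expect_identical(attr(r, "mode"), "ratio")
  expect_equal(as.numeric(normalize_to_mean(c(5, 5, 5), "ratio")),
               c(1, 1, 1))
  set.seed(1)
  cen <- normalize_to_mean(rnorm(50, mean = 3), "centered")
  expect_lt(abs(mean(cen)), 1e-12)
  expect_error(normalize_to_mean(c(-1, 1), "ratio"), "zero mean")
})

test_that("panel preprocessing records the filter warm-up span", {
  panel <- cosine_panel(n_reps = 2)
  det <- preprocess_panel(panel)
  expect_s3_class(det, "ts_set")
  expect_equal(attr(det, "edge_hours"), 12)
  expect_equal(dim(det$signals), dim(panel$signals))
  # detrended output is centered
  expect_lt(max(abs(rowMeans(det$signals))), 1e-12)
})
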