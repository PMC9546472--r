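test_that("a noiseless cosine is recovered exactly", {
  t <- hourly_week()
  y <- 100 + 10 * cos(2 * pi * (t - 6) / 25.5)
  f <- fit_fft_nlls(y, t)
  expect_identical(f$status, "ok")
  expect_lt(abs(f$period_hours - 25.5), 0.01)
  expect_lt(abs(f$phase_hours - 6), 0.01)
  expect_lt(abs(f$amplitude - 10), 0.01)
  expect_lt(f$rae, 0.01)
})

test_that("the circadian component is selected over its harmonic", {
  t <- hourly_week()
  y <- cos(2 * pi * t / 24) + 0.5 * cos(2 * pi * t / 12)
  f <- fit_fft_nlls(y, t)
  expect_identical(f$status, "ok")
  expect_equal(f$period_hours, 24, tolerance = 0.05)
  # the 12-h harmonic is fitted but not selected
  expect_true(any(abs(f$components$period_hours - 12) < 0.5))
})

test_that("no-circadian and degenerate inputs are flagged, not fudged", {
  t <- hourly_week()
  f12 <- fit_fft_nlls(cos(2 * pi * t / 12), t, circadian_window = c(18, 34))
  expect_identical(f12$status, "no_circadian_component")
  fc <- fit_fft_nlls(rep(5, 168), t)
  expect_identical(fc$status, "non_convergent")
  expect_error(fit_fft_nlls(rnorm(30), 0:29), ">= 48")
})

test_that("phase convention: first peak after dawn, circadian-normalized", {
  t <- hourly_week()
  f <- fit_fft_nlls(100 + 10 * cos(2 * pi * (t - 6) / 25.5), t)
  expect_equal(circadian_phase(f, 24), 6 * 24 / 25.5, tolerance = 1e-3)
  expect_equal(circadian_phase(f, NULL), 6, tolerance = 1e-3)
  # normalizing to the fitted period returns the raw phase
  expect_equal(circadian_phase(f, f$period_hours), circadian_phase(f, NULL))
  # peak placed at t = 30 reports the first peak, 30 mod 25.5 = 4.5
  f2 <- fit_fft_nlls(100 + 10 * cos(2 * pi * (t - 30) / 25.5), t)
  expect_equal(circadian_phase(f2, NULL), 4.5, tolerance = 1e-3)
})

test_that("time shifts move the phase and scaling leaves RAE unchanged", {
  t <- hourly_week()
  set.seed(31)
  noise <- rnorm(168, 0, 0.5)
  base <- 100 + 10 * cos(2 * pi * (t - 6) / 25.5)
  f0 <- fit_fft_nlls(base, t)
  for (delta in c(3, 11)) {
    fs <- fit_fft_nlls(100 + 10 * cos(2 * pi * (t - 6 - delta) / 25.5), t)
    expect_equal(circadian_phase(fs, NULL),
                 (6 + delta) %% fs$period_hours, tolerance = 1e-3)
  }
  fn <- fit_fft_nlls(base + noise, t)
  fn_scaled <- fit_fft_nlls(7 * (base + noise), t)
  expect_lt(abs(fn$rae - fn_scaled$rae), 1e-9)
})

test_that("residual sum of squares never increases with model order", {
  t <- hourly_week()
  set.seed(13)
  y <- cos(2 * pi * t / 24) + 0.4 * cos(2 * pi * (t - 3) / 12) + rnorm(168, 0, 0.3)
  rss <- vapply(1:3, function(k) fit_fft_nlls(y, t, max_components = k)$rss,
                numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("RAE is the clipped SE-to-amplitude ratio", {
  fit <- structure(
    list(components = data.frame(period_hours = 24, amplitude = 1,
                                 phase_hours = 0, se_period = 0.1,
                                 se_amplitude = 2, se_phase = 0.1),
         selected = 1L, status = "ok"),
    class = "rhythm_fit")
  expect_equal(relative_amplitude_error(fit), 1)  # se >= amplitude clips
  fit$components$se_amplitude <- 0.25
  expect_equal(relative_amplitude_error(fit), 0.25)
  fit$components$amplitude <- 0
  expect_error(relative_amplitude_error(fit), "zero amplitude")
})

test_that("panel fits trim the recorded filter warm-up before fitting", {
  pz <- preset_ztc(n_reps = 3, seed = 128, T_hours = 28)
  panel <- simulate_panel(pz$params, pz$regime)
  det <- preprocess_panel(panel)
  fits <- fit_panel(det)
  expect_true(all(fits$status == "ok"))
  expect_lt(max(abs(fits$period_hours - 28)), 0.2)
})
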