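test_that("light indicator follows the half-open photoperiod convention", {
  ztc24 <- light_regime("ZTC", T_hours = 24, photoperiod_hours = 12)
  t <- 0:47
  L <- make_light_indicator(ztc24, t)
  expect_equal(L[t == 5], 1)
  expect_equal(L[t == 13], 0)
  expect_equal(L[t == 24], 1)  # second dawn

  ztc20 <- light_regime("ZTC", T_hours = 20, photoperiod_hours = 10)
  L20 <- make_light_indicator(ztc20, 0:39)
  expect_equal(L20[(0:39) == 10], 0)   # boundary: light is [0, 10)
  expect_equal(L20[(0:39) == 9], 1)

  expect_true(all(make_light_indicator(light_regime("FRL"), t) == 1))
  expect_true(all(make_light_indicator(light_regime("FRD"), t) == 0))
})

test_that("non-uniform grids are rejected with the offending interval named", {
  expect_error(
    make_light_indicator(light_regime("ZTC"), c(0, 1, 2, 4, 5)),
    "interval 3")
})

test_that("identical seed regenerates a bit-identical panel", {
  pr <- preset_frl(n_reps = 6, seed = 77)
  a <- simulate_panel(pr$params, pr$regime)
  b <- simulate_panel(pr$params, pr$regime)
  expect_identical(a$signals, b$signals)
  c <- simulate_panel(sim_params(n_reps = 6, seed = 78), pr$regime)
  expect_false(identical(a$signals, c$signals))
})

test_that("degenerate limits reduce to pure cosine and pure baseline", {
  t <- 0:96
  p <- sim_params(n_reps = 3, duration_hours = 96, mu_period_hours = 24,
                  sd_period_hours = 0, mu_phase_hours = 6,
                  sd_phase_hours = 0, amplitude0 = 5,
                  damping_halflife_hours = Inf, baseline0 = 10,
                  baseline_slope = 0, noise_sd = 0, seed = 1)
  panel <- simulate_panel(p, light_regime("FRL"))
  ref <- 10 + 5 * cos(2 * pi * (t - 6) / 24)
  for (j in 1:3) expect_equal(unname(panel$signals[j, ]), ref)

  p0 <- sim_params(n_reps = 2, duration_hours = 96, amplitude0 = 0,
                   baseline0 = 3, baseline_slope = 0.25, noise_sd = 0,
                   seed = 1)
  flat <- simulate_panel(p0, light_regime("FRL"))
  expect_equal(unname(flat$signals[1, ]), 3 + 0.25 * t)
})

test_that("noiseless one-period mean equals baseline midpoint plus light share", {
  # T = 24 ZTC, hourly samples over exactly one cycle (t = 0..23)
  p <- sim_params(n_reps = 1, duration_hours = 71, mu_phase_hours = 6,
                  sd_phase_hours = 0, amplitude0 = 4,
                  damping_halflife_hours = Inf, baseline0 = 50,
                  baseline_slope = 0.5, masking_gain = 8, noise_sd = 0,
                  seed = 1)
  panel <- simulate_panel(p, light_regime("ZTC", T_hours = 24))
  one_cycle <- panel$signals[1, panel$times < 24]
  baseline_mid <- 50 + 0.5 * mean(0:23)
  expect_equal(mean(one_cycle), baseline_mid + 8 * 12 / 24, tolerance = 1e-10)
})

test_that("zeitgeber cycles entrain the simulated period to T", {
  pz <- preset_ztc(n_reps = 5, seed = 3, T_hours = 20)
  panel <- simulate_panel(pz$params, pz$regime)
  expect_equal(attr(panel, "truth")$periods, rep(20, 5))
  # free run draws heterogeneous periods
  pf <- preset_frl(n_reps = 5, seed = 3)
  free <- simulate_panel(pf$params, pf$regime)
  expect_gt(sd(attr(free, "truth")$periods), 0)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(n_reps = 0), "n_reps")
  expect_error(sim_params(damping_halflife_hours = -5), "damping")
  expect_error(sim_params(noise_sd = -1), "noise_sd")
  expect_error(sim_params(duration_hours = 10), "48 samples")
  expect_error(light_regime("ZTC", T_hours = 24, photoperiod_hours = 30),
               "photoperiod")
})
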