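test_that("Fisher combination matches the chi-square closed form", {
  # X = -4 log(0.5) = 2.7726; survival of chi-square df 4 at X is
  # exp(-X/2) (1 + X/2) = 0.5966
  expect_equal(fisher_combine(c(0.5, 0.5)), 0.5966, tolerance = 1e-3)
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.37), 0.37)  # identity at k = 1
  expect_warning(p0 <- fisher_combine(c(0, 0.5)), "clipped")
  expect_true(p0 >= 0 && p0 < 1e-100)
})

test_that("BH q-values equal the step-up definition", {
  # worked example, frozen from the brute-force step-up definition
  expect_equal(bh_qvalues(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 4 * 0.02 / 3, 0.8))
  expect_equal(bh_qvalues(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_qvalues(0.2), 0.2)
  expect_error(bh_qvalues(numeric(0)), "empty")
  # oracle agreement on random vectors
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_qvalues(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("Lomb-Scargle finds a pure period at maximal significance", {
  t <- hourly_week()
  ls <- lomb_scargle_test(cos(2 * pi * t / 24), t, c(18, 34), n_perm = 99,
                          seed = 5)
  expect_equal(ls$best_period, 24, tolerance = 0.1)
  expect_equal(ls$p_ls, 1 / 100)  # add-one permutation floor
  const <- lomb_scargle_test(rep(3, 168), t, c(18, 34), n_perm = 20,
                             seed = 1)
  expect_equal(const$p_ls, 1)
  expect_true(const$degenerate)
  expect_error(lomb_scargle_test(rnorm(168), t, c(1, 34), n_perm = 10,
                                 seed = 1), "period_range")
})

test_that("JTK concordance is maximal on the cosine and symmetric to sign flip", {
  t <- hourly_week()
  # the reference itself (tie structure exactly preserved) is the
  # maximal-concordance input
  y <- round(cos(2 * pi * t / 24), 8)
  jt <- jtk_cycle_test(y, t)
  expect_equal(jt$best_period, 24)
  expect_equal(jt$best_lag, 0)
  expect_equal(jt$tau, 1)
  # the matched reference attains the minimal p over the whole grid
  refs <- circasync:::.jtk_refs(t, seq(18, 34, 2), 2)
  ps <- vapply(refs, function(rf)
    circasync:::.kendall_greater(y, rf$ref)$p, numeric(1))
  expect_equal(min(ps) * length(refs), jt$p_jtk)
  # anti-phase lag on the flipped series, same p
  jt2 <- jtk_cycle_test(-y, t)
  expect_equal(jt2$best_lag, 12)
  expect_equal(jt2$p_jtk, jt$p_jtk)
  expect_equal(jtk_cycle_test(rep(1, 168), t)$p_jtk, 1)
})

test_that("Kendall normal approximation tracks the exhaustive null at n = 8", {
  n <- 8
  ref <- round(cos(2 * pi * (0:7) / 8), 8)
  pairs <- combn(n, 2)
  sgn_ref <- sign(ref[pairs[2, ]] - ref[pairs[1, ]])
  perms <- all_perms(n)
  S_all <- apply(perms, 1, function(x)
    sum(sign(x[pairs[2, ]] - x[pairs[1, ]]) * sgn_ref))
  set.seed(21)
  for (i in 1:50) {
    x <- sample(n)
    S <- sum(sign(x[pairs[2, ]] - x[pairs[1, ]]) * sgn_ref)
    p_exact <- mean(S_all >= S)
    p_approx <- circasync:::.kendall_greater(as.numeric(x), ref)$p
    expect_lt(abs(p_exact - p_approx), 0.08)
  }
})

test_that("rhythmic calls follow the strict q and closed period rules", {
  calls <- data.frame(
    replicate_id = paste0("r", 1:10),
    q = c(rep(1e-5, 6), 0.001, 0.5, 1e-5, 1e-5),
    period_detected_hours = c(rep(24, 6), 24, 24, 17.9, 34.1))
  out <- call_rhythmic(calls, q_threshold = 0.001, period_range = c(18, 34))
  expect_equal(sum(out$rhythmic), 6)
  expect_equal(attr(out, "rhythmic_fraction"), 0.6)
  expect_false(out$rhythmic[7])   # q exactly at threshold is not rhythmic
  expect_false(out$rhythmic[9])   # period below the closed range
  # period exactly at a closed bound is rhythmic
  b <- call_rhythmic(data.frame(replicate_id = "x", q = 1e-5,
                                period_detected_hours = 34))
  expect_true(b$rhythmic)
})

test_that("rhythmic fraction does not increase with noise", {
  fractions <- vapply(c(0.5, 2, 8), function(ns) {
    fr <- vapply(1:6, function(s) {
      pr <- preset_frl(n_reps = 6, seed = 600 + s, noise_sd = ns)
      panel <- simulate_panel(pr$params, pr$regime)
      calls <- detect_rhythms(panel, n_perm = 60, seed = 700 + s)
      attr(calls, "rhythmic_fraction")
    }, numeric(1))
    mean(fr)
  }, numeric(1))
  expect_true(all(diff(fractions) <= 0))
})
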