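test_that("T-cycle phases normalize to the 24-h scale", {
  expect_equal(normalize_phase_to_24(14, 28), 12)
  expect_equal(normalize_phase_to_24(10, 20), 12)
  expect_equal(normalize_phase_to_24(7.3, 24), 7.3)  # T = 24 is identity
  expect_warning(out <- normalize_phase_to_24(25, 24), "modulo")
  expect_equal(out, 1)
  # order within a T-cycle group is preserved
  ph <- c(2, 9, 14, 19.5)
  expect_equal(order(normalize_phase_to_24(ph, 20)), order(ph))
})

test_that("group comparison separates distinct groups with distinct letters", {
  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_lt(same$F_statistic, 1e-10)
  expect_equal(same$tukey_letters, c("a", "a"))

  three <- compare_groups(list(x = c(1, 2, 3), y = c(1, 2, 3),
                               z = c(10, 11, 12)))
  expect_lt(three$p_anova, 0.001)
  expect_equal(three$tukey_letters[1], three$tukey_letters[2])
  expect_false(three$tukey_letters[3] %in% three$tukey_letters[1:2])
})

test_that("degenerate group inputs are rejected", {
  expect_error(compare_groups(list(a = c(1, 2, 3))), "2 groups")
  expect_error(compare_groups(list(a = c(1, 2), b = 3)), "at least 2 values")
  expect_error(compare_groups(list(a = c(1, 1), b = c(1, 1))),
               "zero pooled variance")
})

test_that("letters are invariant to group order and consistent with Tukey p", {
  set.seed(51)
  vals <- list(a = rnorm(8, 0), b = rnorm(8, 0.5), c = rnorm(8, 4),
               d = rnorm(8, 4.2))
  g1 <- compare_groups(vals)
  g2 <- compare_groups(rev(vals))
  # same partition into not-significantly-different sets, whatever the labels
  part <- function(g) {
    shared <- outer(g$tukey_letters, g$tukey_letters,
                    Vectorize(function(x, y)
                      length(intersect(strsplit(x, "")[[1]],
                                       strsplit(y, "")[[1]])) > 0))
    dimnames(shared) <- list(g$group_labels, g$group_labels)
    shared
  }
  p1 <- part(g1)
  p2 <- part(g2)[g1$group_labels, g1$group_labels]
  expect_identical(p1, p2)
  # shared letter exactly when the Tukey pairwise p is at or above alpha
  for (i in 1:3) for (j in (i + 1):4) {
    lab <- g1$group_labels
    expect_identical(unname(p1[i, j]),
                     g1$tukey_p[lab[i], lab[j]] >= g1$alpha)
  }
})

test_that("an injected clock-driven phase offset is detected across T", {
  # pure masking places the peak at the same cycle fraction for every T;
  # shift it for T20 only and the normalized phases must separate
  phases <- list()
  for (cfg in list(list(T = 20, mu = 9), list(T = 24, mu = 6))) {
    pz <- preset_ztc(n_reps = 6, seed = 300 + cfg$T, T_hours = cfg$T)
    pz$params$mu_phase_hours <- cfg$mu
    det <- preprocess_panel(simulate_panel(pz$params, pz$regime))
    fits <- fit_panel(det, circadian_window = c(0.75, 1.25) * cfg$T)
    ok <- fits$status == "ok"
    phases[[paste0("T", cfg$T)]] <-
      normalize_phase_to_24(fits$phase_hours[ok] %% cfg$T, cfg$T)
  }
  gc <- compare_groups(phases)
  expect_lt(gc$p_anova, 0.01)
  expect_false(gc$tukey_letters[1] == gc$tukey_letters[2])
})

test_that("fitted periods track the zeitgeber cycle length", {
  panels <- list()
  for (T in c(20, 24)) {
    pz <- preset_ztc(n_reps = 4, seed = 100 + T, T_hours = T)
    panels[[as.character(T)]] <- simulate_panel(pz$params, pz$regime)
  }
  tab <- period_vs_T(panels, pipeline_config(n_perm = 60, seed = 5))
  expect_equal(tab$T_hours, c(20, 24))
  expect_true(all(abs(tab$mean_period_hours - tab$T_hours) < 0.2))
  expect_true(all(tab$n_rhythmic == 4))
  expect_false(any(tab$degenerate))
})
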