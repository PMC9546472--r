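# Fixture builders shared across test files; everything is generated in
# code so tests carry no stored data.

hourly_week <- function() 0:167

# panel of identical pure cosines (period tau, peak at phi), no noise;
# spans a full week (0..168 h) like the simulated panels
cosine_panel <- function(n_reps = 4, tau = 24, phi = 6, times = 0:168,
                         amp = 10, base = 100) {
  y <- base + amp * cos(2 * pi * (times - phi) / tau)
  time_series_set(times, matrix(rep(y, each = n_reps), nrow = n_reps),
                  regime = light_regime("FRL"), label = "fixture")
}

# trended white-noise panel (the arrhythmic null with thallus growth)
noise_panel <- function(n_reps = 5, seed = 1, slope = 0.5, noise_sd = 1,
                        duration = 168) {
  simulate_panel(
    sim_params(n_reps = n_reps, duration_hours = duration, dt_hours = 1,
               amplitude0 = 0, baseline_slope = slope, noise_sd = noise_sd,
               seed = seed),
    light_regime("FRL"))
}

# brute-force BH step-up from the definition, as an independent oracle
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(m * p[o][i:m] / (i:m))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# all permutations of 1:n (small n), one row each
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
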