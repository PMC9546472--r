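#!/usr/bin/env Rscript
# Generate the synthetic delayed-fluorescence panels for the three light
# conditions (free-running light, free-running darkness, zeitgeber cycles)
# and the four T-cycle lengths, and write them as wide CSVs under results/.
# Every downstream script reads these files, so the whole analysis is
# reproducible from this one seed.

library(circasync)

seed <- 20220603
dir.create("results/panels", recursive = TRUE, showWarnings = FALSE)
seeds <- split_seed(seed, 8)

presets <- list(
  frl = preset_frl(seed = seeds[1]),
  frd = preset_frd(seed = seeds[2]),
  ztc = preset_ztc(seed = seeds[3]))
for (nm in names(presets)) {
  panel <- simulate_panel(presets[[nm]]$params, presets[[nm]]$regime)
  write_timeseries_csv(panel, sprintf("results/panels/%s.csv", nm))
  message(sprintf("%s: %d replicates x %d h, condition %s", nm,
                  nrow(panel$signals), max(panel$times),
                  panel$regime$condition))
}

Ts <- c(20, 22, 24, 28)
for (i in seq_along(Ts)) {
  pz <- preset_ztc(n_reps = 25, seed = seeds[4 + i], T_hours = Ts[i])
  panel <- simulate_panel(pz$params, pz$regime)
  write_timeseries_csv(panel, sprintf("results/panels/t%d.csv", Ts[i]))
}
message("T-cycle panels written for T = ", paste(Ts, collapse = ", "), " h")
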