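#!/usr/bin/env Rscript
# FFT-NLLS rhythm parameters per thallus: period +/- SE, dawn-referenced
# phase (raw and circadian-normalized), amplitude and RAE, estimated on the
# smoothed + BAMP-detrended waveforms of the thalli called rhythmic.

library(circasync)

for (nm in c("frl", "frd", "ztc")) {
  panel <- read_timeseries_csv(sprintf("results/panels/%s.csv", nm))
  calls <- read.csv(sprintf("results/calls_%s.csv", nm))
  det <- preprocess_panel(panel)
  fits <- fit_panel(det)
  fits$rhythmic <- fits$replicate_id %in%
    calls$replicate_id[calls$rhythmic]
  write.csv(fits, sprintf("results/fits_%s.csv", nm), row.names = FALSE)
  ok <- fits$status == "ok" & fits$rhythmic
  message(sprintf(
    "%s: period %.2f +/- %.2f h, RAE %.2f +/- %.2f (n = %d rhythmic)",
    toupper(nm), mean(fits$period_hours[ok]),
    sd(fits$period_hours[ok]) / sqrt(sum(ok)), mean(fits$rae[ok]),
    sd(fits$rae[ok]) / sqrt(sum(ok)), sum(ok)))
}
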