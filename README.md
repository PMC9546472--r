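# circasync

Rhythm analysis for photosynthetic time series: does a panel of replicate
plants show circadian rhythms, how strong and how fast are they, and do the
replicates keep a common phase?

`circasync` implements the full analysis chain used to characterize
circadian and diel rhythms of photosynthesis reporters — delayed
chlorophyll fluorescence (DF) and PAM-derived Y(II)/NPQ — recorded hourly
for about a week from panels of replicate liverwort thalli (or any
comparable organism) under free-running light (FRL), free-running darkness
(FRD), or zeitgeber light/dark cycles (ZTC) of cycle length T:

* **Synthetic panels** (`simulate_panel()`, `preset_frl()` / `preset_frd()`
  / `preset_ztc()`): damped cosines with inter-replicate period/phase
  heterogeneity on a growing baseline, optional additive zeitgeber
  masking, Gaussian noise; seeded and bit-reproducible.
* **Detrending** (`preprocess_panel()`): 5-h moving-average smoothing and
  baseline-and-amplitude (BAMP) detrending (moving-average baseline,
  moving-SD envelope).
* **Rhythmicity calling** (`detect_rhythms()`): per-replicate Lomb–Scargle
  permutation test plus JTK-style Kendall rank test against lagged cosine
  references, Fisher combination, Benjamini–Hochberg q-values, and the
  rhythmic filter q < 0.001 with period in [18, 34] h.
* **FFT-NLLS** (`fit_fft_nlls()`, `fit_panel()`): FFT-seeded multi-cosine
  nonlinear least squares giving period ± SE, dawn-referenced phase,
  amplitude, and the relative amplitude error RAE = se(amplitude)/amplitude
  ∈ [0, 1].
* **Phase synchrony** (`sliding_window_sync()`, `kuramoto_order()`): the
  Kuramoto order parameter `r e^{iψ} = mean(e^{iθ_j})` of the
  circadian-normalized phases, refit over 48-h sliding windows.
* **T-cycle and group statistics** (`period_vs_T()`,
  `normalize_phase_to_24()`, `compare_groups()`): period-vs-T tables,
  phase normalization to the 24-h scale, one-way ANOVA with Tukey HSD and
  compact letter displays.
* **Pipeline and I/O** (`run_pipeline()`, `read_timeseries_csv()`,
  `write_report()`): one call from a raw CSV panel to calls/fits/synchrony
  tables plus a JSON summary, deterministic given one seed.

The methods vignette (`vignettes/rhythm-analysis-methods.Rmd`) documents
the model, every tunable parameter, and the numerical design choices.

## Worked example

```r
library(circasync)

pre   <- preset_frl(seed = 42)                   # 50 thalli, 168 h hourly
panel <- simulate_panel(pre$params, pre$regime)
report <- run_pipeline(panel, pipeline_config(seed = 3))
report
#> <pipeline_report> 50 replicates, 50 rhythmic (100%)
#>   mean period 25.46 +/- 0.25 h, mean RAE 0.02 +/- 0.00
report$sync[, c("window_start_hours", "n_included", "r")]
#>   window_start_hours n_included         r
#> 1                  0         50 0.8437675
#> 2                 24         50 0.8825912
#> 3                 48         50 0.9097575
#> 4                 72         50 0.8314546
#> 5                 96         50 0.7247888
#> 6                120         42 0.2016300
```

All 50 simulated thalli are called rhythmic (q < 0.001), the mean fitted
free-running period (25.46 h) recovers the preset's 25.5-h mean, and the
Kuramoto synchronization index r decays from 0.84 in the first 48-h window
to 0.20 in the last: with a 1.5-h inter-thallus period SD, replicate
phases drift apart over the week — the desynchronization signature of
free-running conditions. Under the ZTC preset the final-window r stays
above 0.9 because the zeitgeber pins every replicate's phase.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → detect → fit → synchrony → T-cycle masking → dose
groups), writing their tables under `results/`.

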