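---
title: "Methods: circadian rhythm detection, FFT-NLLS estimation and phase synchrony"
author: "circasync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian rhythm detection, FFT-NLLS estimation and phase synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circasync)
```

## The problem

Delayed chlorophyll fluorescence (DF) and PAM-derived parameters such as
Y(II) and NPQ are non-invasive reporters of photosynthetic biochemistry.
Recorded hourly over about a week from dozens of replicate thalli, they can
reveal whether photosynthesis is under circadian control: rhythms that
persist under constant conditions (free-running light, FRL; free-running
darkness, FRD) indicate an endogenous clock, while rhythms that slavishly
track an imposed light/dark ("zeitgeber") cycle of non-24-h length T may
simply be driven — *masked* — by the light itself. `circasync` implements
the complete analysis chain for such panels: simulation of realistic
synthetic panels, detrending, rhythmicity calling, period/phase/amplitude
estimation, phase-synchrony quantification, and group statistics.

## The generative model behind the synthetic panels

`simulate_panel()` draws, for replicate thallus $j$,

$$y_j(t) = b_0 + b_1 t
  + a\,2^{-t/\tau_d}\cos\!\big(2\pi (t-\phi_j)/T_j\big)
  + M\,L(t) + \varepsilon_t,$$

with $T_j \sim N(\mu_T, \sigma_T)$, $\phi_j \sim N(\mu_\phi,
\sigma_\phi)$, $\varepsilon_t \sim N(0, \sigma^2)$ i.i.d., and $L(t)$ the
0/1 light indicator (half-open light interval $[{\rm dawn}, {\rm dawn} +
{\rm photoperiod})$). The ingredients mirror what real DF panels show:

* a continuously increasing baseline ($b_0 + b_1 t$), because thalli grow
  during the week of imaging;
* exponential amplitude damping with half-life $\tau_d$ (free-running DF
  rhythms visibly damp over 4–5 days);
* inter-replicate period heterogeneity $\sigma_T$, the mechanism that
  progressively desynchronizes replicate phases under free run;
* under zeitgeber cycles, entrainment: $T_j \equiv T$, $\sigma_T$ is
  ignored, and the mean peak sits at the fixed cycle fraction
  $\mu_\phi/24$, so that the *normalized* phase is comparable across
  T-cycle lengths — this makes the generator a pure *masking* model, with
  an additive, instantaneous light response $M\,L(t)$ and no
  phase-resetting dynamics. A clock contribution can be emulated by
  shifting `mu_phase_hours` per condition.

Free-running darkness is modelled identically to free-running light but
with noisier, faster-damping presets; the brief hourly light exposures
used to elicit DF in darkness are not treated as forcing.

Preset study conditions (`preset_frl()`, `preset_frd()`, `preset_ztc()`)
fix 50 replicates, 168 h of hourly sampling, $\mu_T = 25.5$ h,
$\sigma_T = 1.5$ h under free run, amplitude 10 on a baseline of 100
growing by 0.5 h⁻¹, and damping half-lives of 60 h (FRL), 48 h (FRD) and
none under ZTC with masking gain 5. Period SD and damping rates are not
published quantities; they were chosen once as values that visibly
desynchronize a panel within a week while leaving most replicates
detectable, and are kept fixed.

What the generator does **not** emulate: non-Gaussian and heteroscedastic
measurement noise, non-linear growth trends, intercellular coupling,
phase-resetting entrainment dynamics, and instrument artefacts. Tests that
pass on these panels therefore validate the *statistical machinery*, not
the biology of any particular dataset.

## Detrending: the waveform track

Raw panels are smoothed with a 5-h centered moving average and then
baseline-and-amplitude (BAMP) detrended: a 24-h moving-average baseline is
subtracted and the residual is divided by its 24-h moving-SD envelope
(clamped below at `amplitude_floor`), yielding a dimensionless,
unit-envelope waveform. The exact algorithm behind the BAMP label in
common web tools is unpublished; the form used here is declared and
configurable, and reproduces the intent — remove the growth trend, undo
the damping envelope. Windows truncate at the series ends rather than
padding or reflecting, so no data are fabricated where phase estimates
matter; the price is waveform distortion within half a baseline window of
either end. `preprocess_panel()` records that warm-up span and
`fit_panel()` discards it by default before fitting: without the trim,
edge distortion biases fitted periods by 0.2–0.5 h on week-long panels
(measured on noiseless simulations), an order of magnitude above the
estimator's intrinsic error.

## Rhythmicity calling: which track the tests run on

Each replicate is scored by two complementary tests and the evidence is
combined:

* **Lomb–Scargle**: the normalized periodogram is evaluated on an 18–34-h
  period grid (0.1-h step) and the peak's significance is assessed by
  permutation — `n_perm` random shufflings of the series, add-one
  corrected, seeded per replicate. Exact under exchangeability of the
  input samples.
* **JTK-style rank concordance**: Kendall's $\tau$ between the series and
  lagged cosine references over a period × lag grid (18–34 h step 2;
  2-h lags), with a one-sided p-value from the tie-corrected normal
  approximation to the null of the Kendall S statistic, Bonferroni
  corrected over the grid. The normal approximation replaces the exact
  tabulated null of the original JTK algorithm; at $n = 8$ it agrees with
  exhaustive permutation to within 0.06 and the discrepancy shrinks with
  $n$ (the tests enforce 0.08).

The two p-values are Fisher-combined ($X = -2\sum\log p_i$ against
$\chi^2_{2k}$), BH-adjusted across the panel, and a replicate is called
rhythmic when $q < 0.001$ (strict) with detected period inside the closed
interval [18, 34] h. The combination used is Fisher rather than the
N-statistic integration of the MetaCycle suite, and the ARSER component is
omitted: the periodogram family (LS) and the rank-concordance family (JTK)
are retained, which is the part of the evidence the q-filter actually
exercises at these panel sizes.

**A deliberate design choice:** the tests are applied to the raw signals
after an ordinary least-squares *linear* detrend, not to the smoothed,
BAMP-detrended waveform track. Filtering induces strong serial
correlation, and both nulls above assume none: measured on white-noise
panels, running the tests on the filtered track produced p < 0.05 rates
near 1.0 (Lomb–Scargle) and 0.93 (JTK) instead of 0.05, and even the
envelope-normalized track without smoothing gave 0.15–0.20 — a completely
broken false-positive rate that no downstream q-threshold can repair. The
OLS detrend is a 2-degree-of-freedom projection that removes the growth
trend while leaving the nulls essentially exact (measured: 0.045 at the
0.05 level, KS uniformity p ≈ 0.33). The filtered track remains the input
for waveform display, FFT-NLLS parameter estimation and synchrony, where
no significance statement is attached to individual samples.

## FFT-NLLS: period, phase, amplitude, RAE

`fit_fft_nlls()` removes a linear trend, then grows a sum-of-cosines model
one component at a time: each new component is seeded at the largest
remaining periodogram peak (period refined by profiling the exact linear
least-squares fit over a grid spanning the periodogram's frequency
resolution), and offset plus all component parameters $(A_i, B_i,
\tau_i)$ are refit jointly by Levenberg–Marquardt least squares. Growth
stops at `max_components` (4) or when the newly added component's
amplitude is not distinguishable from zero at 1 σ. The circadian component
is the one with $\tau$ inside the 18–34-h window (largest amplitude if
several); standard errors come from the linearized covariance at the
optimum via the delta method. The **relative amplitude error** is
RAE = se(amplitude)/amplitude of the selected component, clipped to
[0, 1]: 0 marks a robust rhythm, 1 an amplitude indistinguishable from
zero. This 1-σ linearized definition is deterministic and testable; the
original FFT-NLLS literature used joint confidence contours, so absolute
RAE values are comparable only within one convention.

Phase convention: the raw phase is the time of the first fitted peak
after entrained dawn ($t = 0$), modulo the period; for cross-replicate
comparison it is circadian-normalized by $\times\,24/\tau$ (configurable,
e.g. to the T-cycle length for zeitgeber panels). Whether published
phase plots use clock-time or circadian-normalized hours is often left
unstated; the convention here is declared and applied uniformly.

Numerical details: component periods are bounded in $[2.5\,\mathrm{d}t,
4\times\mathrm{span}]$; a constant series returns `non_convergent`; a fit
with no component in the window returns `no_circadian_component`; both
statuses are excluded from downstream means exactly as fits flagged as
errors are excluded in practice.

## Phase synchrony

Phases are mapped to angles $\theta = 2\pi\,({\rm phase}\bmod s)/s$ on the
$s$ = 24-h circle and summarized by the Kuramoto order parameter
$r e^{i\psi} = N^{-1}\sum_j e^{i\theta_j}$: $r = 1$ is absolute synchrony,
$r \to 0$ uniform dispersion, and $\psi$ is the circular mean phase
(never the arithmetic mean of hours). `sliding_window_sync()` refits
FFT-NLLS inside 48-h windows stepped by 24 h starting at 0 h (0–48,
24–72, …, 120–168 on a week-long panel; the start is configurable),
includes only rhythmic replicates whose windowed refit converges with a
circadian component — exclusion is per window, not global — and reports
$r$, $\psi$ and the mean RAE per window, with the included count. Windowed
refits default to a single cosine component: on 2-cycle segments the
fundamental's phase is what the order parameter consumes, and one
component estimates it as accurately as two at less than half the cost
(verified on the presets; $r$ agrees to ~0.02).

## T-cycle analysis and group statistics

Under a zeitgeber cycle of length T, the fitted phase lives on a T-hour
circle; `normalize_phase_to_24()` rescales it by $24/T$ so timing can be
compared across T as a fraction of the cycle. Masking predicts that the
fitted period equals T and that the normalized phase is constant across T;
a circadian contribution predicts systematically earlier normalized phase
under longer T. Group comparisons (`compare_groups()`) use one-way ANOVA
with Tukey's HSD at family α = 0.05 and a compact letter display computed
by insert-and-absorb from the pairwise Tukey p-matrix; phases are treated
as linear quantities after normalization (circular ANOVA is out of scope,
and at the phase dispersions involved the distinction is immaterial).

## Problem sizes used in the checks

The packaged checks run the presets at their native size (50 replicates,
168 h) for the synchrony contrast (50 seeds per condition), 200 five-
replicate noise panels for the false-positive rate, 100 noisy seeds for
period recovery, and 50 seeds of four 8-replicate T-cycle panels for the
masking analysis; the acceptance script uses 25-replicate T-cycle panels
and 100 noise panels. These sizes give the binomial and KS margins used
in the assertions while keeping a full run in minutes.

## Known limitations

* The BAMP form here is a declared reconstruction, not a bit-compatible
  reimplementation of any specific web tool; RAE uses the 1-σ linearized
  convention. Absolute agreement with other software is therefore
  approximate even on identical data.
* The JTK null is a normal approximation; for very short series (< 20
  points) its tail accuracy degrades.
* The LS permutation p has resolution $1/(n_{\rm perm}+1)$; panel-wide
  q-values below $10^{-3}$ at small `n_perm` rely on the JTK contribution
  through the Fisher combination.
* Rhythmicity testing assumes the non-rhythmic null is white noise plus a
  linear trend. Strongly curved growth or autocorrelated instrument noise
  would need a more conservative null; that is flagged, not solved, here.
* The generator's masking is additive and instantaneous, with no
  phase-resetting; it reproduces the period/phase signatures of masking
  but cannot emulate entrainment limits (e.g. loss of locking at extreme
  T).
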