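---
title: "Models and methods behind rodnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rodnoise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodnoise)
```

rodnoise analyses rod photoreceptor physiology at four levels — flash
families, dark noise, ERG and outer-segment morphometry — and ships a
synthetic generator calibrated to cohort-level estimates for a
wild-type / GARP2-knockout strain pair, so that every estimator can be
validated by parameter recovery. This vignette explains the models, the
defaults and the numerical decisions, including the places where the
analysis conventions were genuinely open and we had to choose.

## Flash-family models

### Hill sensitivity

Peak response amplitudes across a flash family follow the Hill relation

$$\frac{R}{R_{max}} = \frac{I^{n}}{I^{n} + I_{0.5}^{n}},$$

with $I$ the flash strength in photoisomerizations per rod (R\*/rod),
$I_{0.5}$ the half-maximal strength (the sensitivity measure, independent
of absolute amplitude) and $n$ the Hill coefficient. `fit_hill()` solves
the nonlinear least-squares problem (Levenberg–Marquardt via minpack.lm)
with $n$ bounded to $[0.1, 10]$ and positivity constraints on the other
parameters; starting values come from the largest amplitude and the
strength closest to half of it. Two degenerate situations are flagged
rather than silently reported: amplitudes with no spread (no information
on $n$) and data that do not span the half-maximal point (fitted $I_{0.5}$
outside the sampled strengths).

### Lamb–Pugh activation and the ensemble fit

The activation phase of the rod flash response follows

$$R(t) = R_{max}\left\{1 - \exp\!\left[-\tfrac{1}{2}\,\Phi\,A\,(t -
t_{delay})^{2}\right]\right\},$$

with $A$ the amplification constant (s$^{-2}$) and $t_{delay}$ a short
transduction delay. `fit_lamb_pugh_ensemble()` fits one shared $(A,
t_{delay})$ across all flashes of a family — the "ensemble" convention —
after baseline subtraction and normalisation by $R_{max}$ (taken from the
family's own Hill fit unless supplied). Only the quadratic-onset model is
physical, so each flash contributes its *leading edge* only. The window
definition is a design choice: from stimulus onset until the response
first reaches 50% of its own peak, capped at 80 ms post-flash. The 50%
rule confines the fit to the activation-dominated phase for every flash
strength; the 80 ms cap protects against dim flashes whose half-peak time
approaches the time-to-peak. Both are exposed (`edge_fraction`,
`edge_max_s`). Whether $t_{delay}$ should be fitted or fixed is not a
settled convention; we fit it jointly by default (bounded to 0–20 ms) and
expose `fix_t_delay` for the fixed-delay variant. Only the product
$\Phi A$ is identified, so mis-scaled photoisomerization estimates rescale
$A$ inversely — the test suite checks this equivariance explicitly.

### Dim-flash recovery

The recovery time constant $\tau_{rec}$ is estimated from the average dim
flash response by a single-exponential fit $a\,e^{-t/\tau}$ to the *final
35%* of the recovery. "Final 35%" we read as *the samples at or below 35%
of peak amplitude* (not the last 35% of recorded time, which depends on
arbitrary trace length and is not robust); the threshold is the
`tail_fraction` argument. The fit runs from the first sample at or below
the threshold until the response returns to baseline (2% of peak) or the
trace ends, seeded by a log-linear regression and refined by nonlinear
least squares — the log-linear seed alone would be biased by additive
noise near zero.

"Dim" itself needs a criterion: we use peak $\le$ 20% of $R_{max}$
(`dim_threshold`), which keeps the response in the quasi-linear range
where recovery is well described by a single exponential. With the default
presets and doubling ladder, the two weakest flashes qualify.

### Peak measurement conventions

Baseline is the mean over the 50 ms before stimulus onset; responses are
analysed as magnitudes after baseline subtraction (stored traces keep
native sign — rod photocurrents are negative-going suppression of the dark
current); ties in the extremum are broken by the earliest sample. A peak
read off a noisy trace as a running extremum carries a small positive
extreme-value bias; at the default noise (0.3 pA on a 23 pA saturating
response) this propagates into a few-percent downward bias of the ensemble
$A$ (≈ −4% over 50 seeded families in the test suite), well inside the
10% recovery tolerance we hold the estimator to.

## Dark-noise pipeline

The continuous ("cellular") dark noise is band-limited to a few hertz, so
it is quantified as the integral of its one-sided power spectral density
over **0.6–10 Hz** (pA²). The instrumental contribution is estimated from
an epoch recorded during a saturating flash, when all CNG channels are
closed and only recording-system noise remains.

One interpretive decision is central: "subtracting the instrumental noise
from the dark noise" is ill-defined sample-by-sample for two stochastic
signals, so the subtraction happens in the *power-spectral domain* —
total and instrumental spectra are estimated with identical settings and
differenced pointwise. Negative post-subtraction densities are retained,
not clamped, so the band integral stays unbiased (a clamp would only be
cosmetic, for plots).

Estimator defaults (`estimate_psd()`): Welch averaged periodogram, Hann
window, 5-s segments, 50% overlap, per-segment linear detrend, one-sided
density normalised by the window power so that Parseval holds
($\int S\,df$ equals the signal variance; enforced to 5% in the tests).
The 5-s segment gives $\Delta f = 0.2$ Hz, resolving the 0.6 Hz band edge;
segments short enough that $\Delta f > 0.3$ Hz are rejected. Band
integration is trapezoidal with linear interpolation at the partial edge
bins, and the cumulative power curve uses the same quadrature so its
endpoint equals the band power exactly. The saturated epoch is trimmed
0.5 s after flash onset to drop the response transient. Per-segment
detrending removes a little true power below ~0.5 Hz and leaks a small
deficit into the band edge; with the default settings this is a
few-percent downward effect, inside the 10–15% tolerances used throughout.
Spectra are subtracted per cell and only then averaged across cells.

## ERG analysis

The a-wave is measured baseline-to-trough and the b-wave trough-to-peak —
the standard ERG convention; whether the b-wave should instead be
referenced to baseline is exposed as `b_from = "baseline"`. Search windows
(a: 5–80 ms, b: 20–300 ms post-flash) are ours and configurable. A trace
whose extrema are in the wrong order (trough after peak) is rejected as
inverted polarity. Intensity-response relations per wave reuse
`fit_hill()`, reporting $V_{max}$ (µV) and $I_{0.5}$ (cd·s/m²); across all
packaged presets the b-wave is far more sensitive than the a-wave
(~50-fold lower $I_{0.5}$), which the tests assert as an invariant.

## Outer-segment morphometry

Lengths are binned into right-open 2-µm bins aligned to 0 and normalized
to frequencies summing to 1. `fit_gaussians()` fits one or two components
$h\,\exp[-4\ln 2\,(x-c)^2/w^2]$ (centre $c$, FWHM $w$, height $h$) to the
bin-centre/frequency pairs; empty bins participate with frequency 0. For
two components, initial centres come from 2-means on a frequency-weighted
pseudo-sample of the bin centres, widths from within-cluster SDs, and the
fitted components are returned ordered by centre; a fit whose centres fall
within one bin width is flagged as collapsed. No constraint ties the two
FWHMs. Component area uses the closed form $h\,w\sqrt{\pi/(4\ln 2)}$
(checked against numerical integration to $10^{-6}$ relative), and
`area_fraction()` reports the share of total fitted area in the
larger-mean component — the long-outer-segment fraction.

## Group statistics

Two-way ANOVA uses genotype × age with interaction and *type-II* sums of
squares, computed by nested model comparison (each main effect after the
other, the interaction after both); this equals the classical table on
balanced designs and remains sensible for the mildly unbalanced cell
counts typical of cohort data. Pairwise genotype contrasts within each age
are Bonferroni-adjusted by the number of contrasts. Band-power
distributions are compared with the tie-corrected Kruskal–Wallis test.
`t_test_from_summary()` reproduces unpaired two-tailed t tests from
published mean ± SD (n) summaries (Welch by default, pooled available) —
useful for checking printed comparisons. The Z-score outlier filter is
single-pass with a default threshold of 2 (none is standard; 2 is
conservative and configurable); note the attainable $|z|$ is bounded by
$(n-1)/\sqrt{n}$, so small samples can never trigger large thresholds.

## The synthetic generator

The generator encodes the cohort-level estimates as ground truth
(`genotype_preset()`): Hill parameters, $R_{max}$, $A$ = 3.8/3.9 s$^{-2}$
(wild-type/knockout), $\tau_{rec}$ = 251/233 ms, band powers 0.17/0.07 pA²
at PM3 (and the corresponding PM6/PM9 values), ERG $V_{max}$ and
$I_{0.5}$ per wave, and outer-segment mixtures (wild-type: single
component at 27.5 µm; knockout: 26.8 µm/FWHM 7.2, weight 0.77 and
34.0 µm/FWHM 7.0, weight 0.23). Acquisition defaults mirror the recording
conditions: 10 kHz sampling with 300 Hz low-pass for currents, 2 kHz with
50 Hz low-pass for ERG, flash strengths doubling from 2 to 256 R\*/rod,
0.2 s of pre-stimulus baseline.

Choices the data model does not dictate:

* **Activation–recovery cross-fade.** Activation and recovery are fitted
  separately in practice and no full-response model is implied; the
  generator joins the Lamb–Pugh rise to the exponential recovery with a
  raised-cosine blend over 10 ms centred at the time the rise reaches its
  Hill-predicted peak. This leaves both fitted regimes untouched and keeps
  noise-free peaks within a few tenths of a percent of the Hill relation
  (5% is the contract).
* **Cellular noise spectrum.** Continuous rod noise is band-limited to a
  few hertz, so the cellular component is Gaussian white noise shaped by a
  2-pole Butterworth low-pass with 3 dB corner at 3 Hz, then rescaled
  analytically (via the filter's squared magnitude response) so its
  *expected* 0.6–10 Hz band power equals the preset value. Only the band
  power is contract-level; the spectral shape is a free choice, and the
  corner is configurable. Discrete (thermal-isomerization) noise events
  are not simulated — the analyses target continuous noise only.
* **Instrumental noise** is white with SD 1 pA in both epochs; the
  subtraction property (doubling it leaves recovered cellular power
  unchanged in expectation) is tested by Monte-Carlo.
* **Recording noise** on flash responses is additive Gaussian, SD 0.3 pA,
  low-passed at 300 Hz to mirror acquisition filtering.
* **ERG templates** are raised-cosine lobes with compact support (a-wave
  trough at 30 ms, b-wave peak at 150 ms), scaled so a noise-free trace
  measured by `measure_erg_waves()` returns the generating Hill amplitudes
  exactly. They emulate amplitudes and ordering, not true ERG waveshape.
* **Seeding.** One master seed per simulation; per-cell streams are
  derived by fixed offsets, making every output reproducible
  byte-for-byte.

What passing recovery tests on these synthetics does *not* show: real
recordings have drifting baselines, correlated (not white-after-filter)
recording noise, cell-to-cell parameter scatter, discrete noise events,
and ERG oscillatory potentials. The generator validates the estimators'
correctness and calibration, not their robustness to every artefact of
acquisition.

## Problem sizes and determinism

The standing test and acceptance runs use sizes chosen to give stable
Monte-Carlo averages at interactive run times: 10–50 seeded flash families
for gain recovery, 20 seeds for recovery-τ and for each genotype's noise
pipeline (60-s dark epochs in the acceptance run, 20–30 s in unit tests),
10⁴–10⁵ mixture draws for morphometry, and 1000 null replicates for the
type-I-error calibration of ANOVA and Kruskal–Wallis at α = 0.05. All
random draws are seeded, so every reported number is reproducible.

## Known limitations

* Hill and Lamb–Pugh fits assume averaged, artefact-free responses;
  there is no outlier rejection at the trace level.
* The band-power estimate inherits the small negative bias of per-segment
  detrending near the lower band edge.
* `fit_gaussians()` with two heavily overlapping components of very
  unequal weight can be ill-conditioned on coarse (2-µm) histograms; the
  collapse flag marks, but cannot repair, such fits.
* Flash strengths are taken as given in R*/rod; no conversion from
  cd·s/m² (which needs the rod collecting area) is attempted.
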