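# rodnoise

Analysis toolkit for rod photoreceptor physiology, built for studies that
compare wild-type and knockout cohorts across flash-family patch-clamp
recordings, dark-noise recordings, scotopic ERG series and outer-segment
morphometry. Every analysis stage is paired with a calibrated synthetic
generator, so the whole pipeline can be validated by parameter recovery
without access to raw animal recordings.

## What it computes

**Sensitivity (Hill fit).** Flash-family peak amplitudes are fitted with
the Hill intensity-response relation

    R / R_max = I^n / (I^n + I_0.5^n)

giving the half-maximal flash strength *I*₀.₅ (R\*/rod), the Hill
coefficient *n* and the saturating amplitude *R*max.

**Phototransduction gain (Lamb–Pugh ensemble fit).** The leading edges of
all flashes in a family are fitted jointly with the activation model

    R(t) = R_max · {1 − exp[−½ · Φ · A · (t − t_delay)²]}

sharing one amplification constant *A* (s⁻²) and delay *t*_delay across
flashes, where Φ is the number of photoisomerizations per rod. Each flash
contributes only its activation-dominated window (up to 50% of its own
peak, capped at 80 ms).

**Recovery kinetics.** The recovery time constant τ_rec comes from a
single-exponential fit to the final portion of the average dim-flash
response — the samples at or below 35% of peak.

**Dark noise.** The continuous cellular dark noise is isolated by spectral
subtraction: Welch power spectra (Hann window, 5-s segments, 50% overlap,
per-segment linear detrend) of a dark epoch and of a light-saturated epoch
(instrumental noise only, all CNG channels closed), subtracted pointwise,
then integrated over 0.6–10 Hz (trapezoidal, with band-edge interpolation).

**ERG.** a-wave (baseline-to-trough) and b-wave (trough-to-peak)
amplitudes per flash strength, each wave's intensity-response fitted with
the same Hill machinery to give *V*max and *I*₀.₅.

**Morphometry.** Outer-segment lengths are binned into 2-µm normalized
histograms and fitted with one or two Gaussian components
(centre, FWHM, height); component areas use the closed form
`height · FWHM · sqrt(π / (4 ln 2))`, and the area fraction of the
longer-mean component quantifies the long-outer-segment population.

**Group statistics.** Two-way ANOVA (genotype × age, type-II sums of
squares) with Bonferroni-corrected genotype contrasts, Kruskal–Wallis for
band-power distributions, unpaired two-tailed t tests recomputable from
published mean ± SD (n) summaries, a Z-score outlier filter, and
mean ± SD (n) summary tables with significance stars.

## Worked example

```r
library(rodnoise)

preset <- genotype_preset("WT", "PM3")      # wild-type generating parameters
fam    <- generate_flash_family(preset, simulation_config(seed = 1))

peaks <- sapply(fam$responses, function(tr) measure_flash_metrics(tr)$I_max)
fit_hill(fam$stimuli, peaks)
#> <hill_fit> I_half 21.31, n 1.17, R_max 24.27 (resid 0.504)

fit_lamb_pugh_ensemble(fam)
#> <lamb_pugh_fit> A 3.65 s^-2, t_delay 3.03 ms, R_max 24.3 (resid 0.837)

fit_recovery_tau(average_dim_flash_response(fam, r_max = 24.27), r_max = 24.27)
#> <recovery_fit> tau_rec 251.4 ms (2587 points from index 4310)

analyze_noise(generate_dark_recording(preset, simulation_config(seed = 1)))
#> <noise_result> cellular band power 0.1555 pA^2 over 0.6-10 Hz
```

The generating values for this preset are I₀.₅ = 20.8 R\*/rod, n = 1.3,
R_max = 23.4 pA, A = 3.8 s⁻², τ_rec = 251 ms and a cellular band power of
0.17 pA²: each single-cell estimate above recovers its generating value to
within the scatter expected at the default recording noise, and averaging
over seeds converges on the generating values (see the tests and the
methods vignette).

`run_pipeline("out/")` runs the full simulate → analyse → report loop for
a wild-type/knockout pair and writes per-cell TSV tables plus a
mean ± SD (n) summary table.

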