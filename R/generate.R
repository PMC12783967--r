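# Synthetic-recording generator. Each generator inverts the corresponding
# analysis model so that parameter recovery is a ground-truth test: flash
# responses follow the Lamb-Pugh activation joined to an exponential
# recovery, dark recordings carry band-calibrated shaped Gaussian cellular
# noise plus white instrumental noise, outer-segment lengths are Gaussian
# mixture draws, and ERG traces have Hill-scaled a/b lobes.

# squared magnitude of a digital filter's frequency response at f (Hz)
.filter_gain2 <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- outer(z, seq_along(filt$b) - 1, `^`) %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1, `^`) %*% filt$a
  as.numeric(Mod(num / den)^2)
}

# white noise low-pass shaped by a 2-pole Butterworth and rescaled so its
# expected one-sided band power over [f_lo, f_hi] equals `band_power`.
# The white-noise one-sided density is 2*sigma^2/fs, so
#   band_power = sigma^2 * (2/fs) * integral |H(f)|^2 df
.shaped_cellular_noise <- function(n, fs, band_power, corner_hz = 3,
                                   f_lo = 0.6, f_hi = 10) {
  if (band_power == 0) return(numeric(n))
  filt <- signal::butter(2, corner_hz / (fs / 2))
  f <- seq(f_lo, f_hi, by = 0.01)
  g2 <- .filter_gain2(filt, f, fs)
  gain_int <- sum(diff(f) * (g2[-1] + g2[-length(g2)]) / 2)
  sigma <- sqrt(band_power / ((2 / fs) * gain_int))
  warm <- round(5 * fs)
  x <- stats::rnorm(n + warm, sd = sigma)
  y <- as.numeric(signal::filter(filt, x))
  y[(warm + 1):(warm + n)]
}

# white noise low-passed at `cutoff` then rescaled back to sd `sd`
.recording_noise <- function(n, fs, sd, cutoff) {
  if (sd == 0) return(numeric(n))
  filt <- signal::butter(2, cutoff / (fs / 2))
  y <- signal::filtfilt(filt, stats::rnorm(n))
  sd * y / stats::sd(y)
}

.hill_fraction <- function(I, I_half, n) I^n / (I^n + I_half^n)

# noise-free flash response: Lamb-Pugh rise cross-faded (raised cosine over
# 10 ms, centred at the time the rise reaches its Hill-predicted peak) into
# a single-exponential recovery. Positive-going; callers set the sign.
.flash_waveform <- function(t_post, phi, preset) {
  A <- preset$gain_A; td <- preset$t_delay
  tau <- preset$tau_rec / 1000
  frac <- .hill_fraction(phi, preset$I_half, preset$hill_n)
  r_peak <- preset$R_max * frac
  act <- lamb_pugh_model(t_post, phi, A, td, preset$R_max)
  t_peak <- td + sqrt(-2 * log(1 - frac) / (phi * A))
  rec <- r_peak * exp(-(t_post - t_peak) / tau)
  h <- 0.005
  w <- ifelse(t_post <= t_peak - h, 0,
              ifelse(t_post >= t_peak + h, 1,
                     0.5 * (1 - cos(pi * (t_post - (t_peak - h)) / (2 * h)))))
  (1 - w) * act + w * rec
}

#' Generate a synthetic rod flash family
#'
#' Builds one cell's averaged flash-family responses from a genotype/age
#' preset: for each flash strength Phi the activation phase follows the
#' Lamb-Pugh model R(t) = R_max (1 - exp(-0.5 Phi A (t - t_delay)^2)),
#' cross-faded into a single-exponential recovery with the preset time
#' constant at the time the rise reaches its Hill-predicted peak
#' R_max Phi^n / (Phi^n + I_half^n). Low-pass-shaped Gaussian recording
#' noise is added, and traces are stored negative-going (suppression of the
#' circulating dark current).
#'
#' @param preset A [genotype_preset()].
#' @param config A [simulation_config()]; `config$duration` must be at least
#'   `t_delay + 5 tau_rec`.
#' @param cell_index Integer; offsets the seed so multi-cell simulations get
#'   independent noise streams.
#' @return A [flash_family()] whose noise-free peak amplitudes follow the
#'   preset Hill relation to within a few percent (the cross-fade rounds the
#'   peak slightly).
#' @examples
#' fam <- generate_flash_family(genotype_preset("WT", "PM3"),
#'                              simulation_config(seed = 1))
#' fam
#' @export
generate_flash_family <- function(preset, config = simulation_config(),
                                  cell_index = 1L) {
  stopifnot(inherits(preset, "genotype_preset"),
            inherits(config, "simulation_config"))
  tau_s <- preset$tau_rec / 1000
  if (config$duration < preset$t_delay + 5 * tau_s)
    stop(sprintf("duration %.3g s is shorter than t_delay + 5*tau_rec = %.3g s",
                 config$duration, preset$t_delay + 5 * tau_s))
  top <- .hill_fraction(max(config$flash_ladder), preset$I_half, preset$hill_n)
  if (top < 0.95)
    warning(sprintf("largest flash reaches only %.0f%% of R_max; ladder may not saturate",
                    100 * top))
  set.seed(config$seed + 7919L * (cell_index - 1L))
  fs <- config$sampling_rate
  n_pre <- round(config$pre_stimulus * fs)
  n_post <- round(config$duration * fs)
  t_post <- (seq_len(n_post) - 1) / fs
  responses <- lapply(config$flash_ladder, function(phi) {
    r <- c(numeric(n_pre), .flash_waveform(t_post, phi, preset))
    noise <- .recording_noise(length(r), fs, config$noise_sd,
                              config$lowpass_cutoff)
    rod_trace(-r + noise, sampling_rate = fs,
              lowpass_cutoff = config$lowpass_cutoff,
              t0 = n_pre + 1L, kind = "rod_current")
  })
  flash_family(config$flash_ladder, responses,
               cell_metadata(preset$label, preset$age))
}

#' Generate a synthetic dark-noise recording
#'
#' Emulates the dark-noise protocol: a long epoch in complete darkness whose
#' current carries both cellular and instrumental noise, followed by an
#' epoch during a saturating flash (all CNG channels closed) carrying
#' instrumental noise only. The cellular component is Gaussian noise shaped
#' by a 2-pole low-pass (3 dB corner 3 Hz) and rescaled so its expected
#' one-sided power over 0.6-10 Hz equals `preset$cellular_band_power`; the
#' instrumental component is white with SD `preset$instrument_sd` in both
#' epochs.
#'
#' @param preset A [genotype_preset()].
#' @param config A [simulation_config()] (supplies sampling rate and seed).
#' @param dark_duration Dark-epoch duration, s (>= 20 so Welch averaging
#'   resolves 0.6 Hz with several segments).
#' @param sat_duration Saturated-epoch duration, s.
#' @param corner_hz 3 dB corner of the cellular shaping filter, Hz.
#' @return A list of class `noise_recording` with `dark_epoch` and
#'   `saturated_epoch` traces and `metadata`.
#' @export
generate_dark_recording <- function(preset, config = simulation_config(),
                                    dark_duration = 60, sat_duration = 20.5,
                                    corner_hz = 3) {
  stopifnot(inherits(preset, "genotype_preset"))
  if (dark_duration < 20)
    stop("dark epoch must be >= 20 s")
  set.seed(config$seed)
  fs <- config$sampling_rate
  n_dark <- round(dark_duration * fs)
  n_sat <- round(sat_duration * fs)
  cellular <- .shaped_cellular_noise(n_dark, fs, preset$cellular_band_power,
                                     corner_hz = corner_hz)
  dark <- cellular + stats::rnorm(n_dark, sd = preset$instrument_sd)
  sat <- stats::rnorm(n_sat, sd = preset$instrument_sd)
  structure(list(dark_epoch = rod_trace(dark, fs, lowpass_cutoff = 300,
                                        kind = "rod_current"),
                 saturated_epoch = rod_trace(sat, fs, lowpass_cutoff = 300,
                                             kind = "rod_current"),
                 metadata = cell_metadata(preset$label, preset$age)),
            class = "noise_recording")
}

#' @export
print.noise_recording <- function(x, ...) {
  cat(sprintf("<noise_recording> %s %s: dark %.3g s + saturated %.3g s @ %g Hz\n",
              x$metadata$genotype, x$metadata$age,
              length(x$dark_epoch$samples) / x$dark_epoch$sampling_rate,
              length(x$saturated_epoch$samples) / x$saturated_epoch$sampling_rate,
              x$dark_epoch$sampling_rate))
  invisible(x)
}

#' Draw synthetic rod outer segment lengths
#'
#' I.i.d. draws from the preset's Gaussian mixture of outer-segment lengths
#' (component FWHM converted to SD via sigma = FWHM / (2 sqrt(2 ln 2))).
#'
#' @param preset A [genotype_preset()].
#' @param n Number of lengths to draw (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of lengths in um.
#' @export
generate_ros_lengths <- function(preset, n, seed = 1L) {
  stopifnot(inherits(preset, "genotype_preset"), n >= 1)
  m <- preset$ros_mixture
  set.seed(seed)
  comp <- sample.int(nrow(m), n, replace = TRUE, prob = m$weight)
  stats::rnorm(n, mean = m$mean[comp], sd = fwhm_to_sd(m$fwhm[comp]))
}

#' Convert between FWHM and Gaussian SD
#'
#' @param fwhm,sd Full width at half maximum / standard deviation.
#' @return The corresponding SD or FWHM (factor 2 sqrt(2 ln 2)).
#' @export
fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhm_to_sd
#' @export
sd_to_fwhm <- function(sd) sd * 2 * sqrt(2 * log(2))

#' Generate a synthetic scotopic ERG trace
#'
#' Template ERG waveform for one flash strength: a negative a-wave lobe
#' (photoreceptor) whose baseline-to-trough amplitude follows
#' Hill(strength; erg_a_vmax, erg_a_ihalf), followed by a positive b-wave
#' lobe (bipolar) whose trough-to-peak amplitude follows the b-wave Hill
#' relation. Lobes are raised-cosine with compact support (a: 10-50 ms,
#' trough 30 ms; b: 50-250 ms, peak 150 ms) so a zero-noise trace measured
#' by [measure_erg_waves()] returns the generating amplitudes exactly.
#'
#' @param preset A [genotype_preset()].
#' @param strength Flash strength in cd.s/m2, within the 0.001-120 ladder.
#' @param sampling_rate Hz (ERG standard 2 kHz, 50 Hz filtered).
#' @param pre_stimulus,duration Pre-/post-stimulus durations, s.
#' @param noise_sd Additive white noise SD in uV (0 for a noise-free trace).
#' @param seed Seed used when `noise_sd > 0`.
#' @return A [rod_trace()] of kind `"erg_voltage"`.
#' @export
generate_erg_trace <- function(preset, strength, sampling_rate = 2000,
                               pre_stimulus = 0.05, duration = 0.35,
                               noise_sd = 0, seed = 1L) {
  stopifnot(inherits(preset, "genotype_preset"))
  if (strength < 0.001 || strength > 120)
    stop("strength must lie within the 0.001-120 cd.s/m2 ladder")
  a_amp <- preset$erg_a_vmax *
    .hill_fraction(strength, preset$erg_a_ihalf, preset$erg_hill_n)
  b_amp <- preset$erg_b_vmax *
    .hill_fraction(strength, preset$erg_b_ihalf, preset$erg_hill_n)
  fs <- sampling_rate
  n_pre <- round(pre_stimulus * fs)
  t_post <- (seq_len(round(duration * fs)) - 1) / fs
  lobe <- function(t, lo, hi) ifelse(t >= lo & t <= hi,
                                     0.5 * (1 - cos(2 * pi * (t - lo) / (hi - lo))),
                                     0)
  v <- -a_amp * lobe(t_post, 0.010, 0.050) +
    (b_amp - a_amp) * lobe(t_post, 0.050, 0.250)
  v <- c(numeric(n_pre), v)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  rod_trace(v, fs, lowpass_cutoff = 50, t0 = n_pre + 1L, kind = "erg_voltage")
}

#' Generate a full synthetic ERG intensity series
#'
#' @param preset A [genotype_preset()].
#' @param strengths Flash strengths in cd.s/m2; the default spans the
#'   0.001-120 ladder logarithmically.
#' @param ... Passed to [generate_erg_trace()].
#' @return A list of class `erg_series` with `strengths`, `traces` and
#'   `metadata`.
#' @export
generate_erg_series <- function(preset,
                                strengths = 10^seq(-3, log10(120), length.out = 12),
                                ...) {
  traces <- lapply(strengths, function(s) generate_erg_trace(preset, s, ...))
  structure(list(strengths = strengths, traces = traces,
                 metadata = cell_metadata(preset$label, preset$age)),
            class = "erg_series")
}
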