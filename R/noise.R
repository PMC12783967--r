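# Dark-noise pipeline: Welch power spectra of the dark and light-saturated
# epochs, pointwise spectral subtraction to isolate the cellular component,
# and the cumulative band power over 0.6-10 Hz. Spectra are one-sided in
# pA^2/Hz; subtraction happens in the power-spectral domain (the saturated
# epoch estimates instrumental noise with all transduction channels closed).

#' Welch power spectral density estimate
#'
#' Averaged-periodogram (Welch) estimate: the trace is cut into
#' `segment_length`-second segments with fractional `overlap`, each segment
#' is linearly detrended and Hann-windowed, and one-sided periodograms are
#' averaged. Density is normalised by the window power so that the integral
#' of the density equals the variance of the (windowed, detrended) signal
#' (Parseval). The frequency grid runs from the resolution
#' `delta_f = 1/segment_length` to Nyquist; `delta_f` must be <= 0.3 Hz so
#' the 0.6 Hz band edge is resolved.
#'
#' @param trace A [rod_trace()] at least two segments long.
#' @param segment_length Segment length, s.
#' @param overlap Fractional overlap between consecutive segments in [0, 1).
#' @return A list of class `power_spectrum`: `frequencies` (Hz), `density`
#'   (pA^2/Hz), `n_segments_averaged`, `delta_f`.
#' @export
estimate_psd <- function(trace, segment_length = 5, overlap = 0.5) {
  stopifnot(inherits(trace, "rod_trace"), overlap >= 0, overlap < 1)
  fs <- trace$sampling_rate
  L <- round(segment_length * fs)
  x <- trace$samples
  if (length(x) < 2 * L)
    stop("trace must be at least 2 segments long")
  delta_f <- fs / L
  if (delta_f > 0.3)
    stop(sprintf("segment too short: delta_f = %.3g Hz > 0.3 Hz cannot resolve the 0.6 Hz band edge",
                 delta_f))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))  # Hann
  norm <- fs * sum(w^2)
  half <- L %/% 2
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    tt <- seq_len(L)
    seg <- stats::.lm.fit(cbind(1, tt), seg)$residuals  # linear detrend
    X <- stats::fft(w * seg)
    pxx <- (Mod(X[2:(half + 1)])^2) / norm
    pxx <- 2 * pxx
    if (L %% 2 == 0) pxx[half] <- pxx[half] / 2  # Nyquist bin not doubled
    acc <- acc + pxx
  }
  structure(list(frequencies = delta_f * seq_len(half),
                 density = acc / length(starts),
                 n_segments_averaged = length(starts), delta_f = delta_f),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, delta_f %.3g Hz, %d segments averaged\n",
              length(x$frequencies), x$delta_f, x$n_segments_averaged))
  invisible(x)
}

#' Subtract the instrumental spectrum from the total spectrum
#'
#' Pointwise difference of two spectra on identical frequency grids.
#' Negative values are retained (not clamped) so band integrals of the
#' cellular spectrum remain unbiased.
#'
#' @param total,instrumental `power_spectrum` objects on the same grid.
#' @return A `power_spectrum` of the difference.
#' @export
subtract_instrumental <- function(total, instrumental) {
  stopifnot(inherits(total, "power_spectrum"),
            inherits(instrumental, "power_spectrum"))
  if (length(total$frequencies) != length(instrumental$frequencies) ||
      any(abs(total$frequencies - instrumental$frequencies) > 1e-9))
    stop("frequency grids differ; refusing to resample silently")
  structure(list(frequencies = total$frequencies,
                 density = total$density - instrumental$density,
                 n_segments_averaged = min(total$n_segments_averaged,
                                           instrumental$n_segments_averaged),
                 delta_f = total$delta_f),
            class = "power_spectrum")
}

# trapezoidal integral of (f, s) between a and b with linear interpolation
# at the partial edge bins
.trapz_band <- function(f, s, a, b) {
  inside <- which(f > a & f < b)
  fa <- stats::approx(f, s, xout = a)$y
  fb <- stats::approx(f, s, xout = b)$y
  ff <- c(a, f[inside], b)
  ss <- c(fa, s[inside], fb)
  sum(diff(ff) * (ss[-1] + ss[-length(ss)]) / 2)
}

#' Band power of a spectrum
#'
#' Trapezoidal integral of the density over `[f_lo, f_hi]`, with linear
#' interpolation at the band edges. The default band 0.6-10 Hz is the one
#' over which continuous rod dark noise is quantified.
#'
#' @param psd A `power_spectrum`.
#' @param f_lo,f_hi Band edges, Hz; the grid must cover them.
#' @return Band power in pA^2.
#' @export
band_power <- function(psd, f_lo = 0.6, f_hi = 10) {
  stopifnot(inherits(psd, "power_spectrum"), f_lo < f_hi)
  f <- psd$frequencies
  if (f_lo < f[1] || f_hi > f[length(f)])
    stop("band lies outside the frequency grid")
  .trapz_band(f, psd$density, f_lo, f_hi)
}

#' Cumulative band-power curve
#'
#' Running trapezoidal integral of the density from `f_lo` upward; the
#' curve's endpoint equals `band_power(psd, f_lo, f_hi)` by construction
#' (same quadrature).
#'
#' @param psd A `power_spectrum`.
#' @param f_lo,f_hi Band edges, Hz.
#' @return A data frame with `frequency` (Hz) and `cumulative_power` (pA^2).
#' @export
cumulative_power_curve <- function(psd, f_lo = 0.6, f_hi = 10) {
  stopifnot(inherits(psd, "power_spectrum"), f_lo < f_hi)
  f <- psd$frequencies
  if (f_lo < f[1] || f_hi > f[length(f)])
    stop("band lies outside the frequency grid")
  inside <- which(f > f_lo & f < f_hi)
  ff <- c(f_lo, f[inside], f_hi)
  ss <- c(stats::approx(f, psd$density, xout = f_lo)$y, psd$density[inside],
          stats::approx(f, psd$density, xout = f_hi)$y)
  steps <- diff(ff) * (ss[-1] + ss[-length(ss)]) / 2
  data.frame(frequency = ff, cumulative_power = c(0, cumsum(steps)))
}

#' Full dark-noise analysis of one recording
#'
#' Runs the complete pipeline on a dark/saturated epoch pair: detrend each
#' epoch (mean and linear drift), estimate both PSDs with identical Welch
#' settings, subtract the instrumental (saturated-epoch) spectrum from the
#' total dark spectrum, and integrate the cellular spectrum over the band.
#' The saturated epoch is trimmed by `sat_trim` seconds after flash onset to
#' exclude the response transient.
#'
#' @param recording A `noise_recording` (see [generate_dark_recording()]).
#' @param segment_length,overlap Welch settings, see [estimate_psd()].
#' @param f_lo,f_hi Analysis band, Hz.
#' @param sat_trim Seconds trimmed from the start of the saturated epoch.
#' @return A list of class `noise_result`: `total_psd`, `instrumental_psd`,
#'   `cellular_psd`, `band`, `cumulative_power` (pA^2), `cumulative_curve`.
#' @export
analyze_noise <- function(recording, segment_length = 5, overlap = 0.5,
                          f_lo = 0.6, f_hi = 10, sat_trim = 0.5) {
  stopifnot(inherits(recording, "noise_recording"))
  dark <- recording$dark_epoch
  sat <- recording$saturated_epoch
  if (dark$sampling_rate != sat$sampling_rate)
    stop("epochs must share one sampling rate")
  n_trim <- round(sat_trim * sat$sampling_rate)
  sat_s <- sat$samples[(n_trim + 1):length(sat$samples)]
  sat <- rod_trace(sat_s, sat$sampling_rate, sat$lowpass_cutoff, kind = sat$kind)
  total <- estimate_psd(dark, segment_length, overlap)
  instr <- estimate_psd(sat, segment_length, overlap)
  cellular <- subtract_instrumental(total, instr)
  curve <- cumulative_power_curve(cellular, f_lo, f_hi)
  structure(list(total_psd = total, instrumental_psd = instr,
                 cellular_psd = cellular, band = c(f_lo, f_hi),
                 cumulative_power = curve$cumulative_power[nrow(curve)],
                 cumulative_curve = curve),
            class = "noise_result")
}

#' @export
print.noise_result <- function(x, ...) {
  cat(sprintf("<noise_result> cellular band power %.4g pA^2 over %.2g-%.2g Hz\n",
              x$cumulative_power, x$band[1], x$band[2]))
  invisible(x)
}
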