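# Scotopic ERG analysis: a-/b-wave amplitude measurement and Hill
# intensity-response fits per wave. Conventions: the a-wave is measured
# baseline-to-trough, the b-wave trough-to-peak (the standard ERG reading;
# a baseline-to-peak variant is available behind a flag).

#' Measure ERG a- and b-wave amplitudes
#'
#' The a-wave amplitude is the baseline minus the trace minimum within the
#' a-search window (default 5-80 ms post-flash); the b-wave amplitude is the
#' maximum within the b-search window (default 20-300 ms) measured from the
#' a-trough value (`b_from = "trough"`, default) or from baseline
#' (`b_from = "baseline"`).
#'
#' @param trace A [rod_trace()] of kind `"erg_voltage"` with >= 20 ms of
#'   pre-flash baseline.
#' @param a_window,b_window Search windows post-flash, s.
#' @param b_from `"trough"` or `"baseline"`.
#' @return A list with `a_amplitude`, `b_amplitude` (uV), `a_trough_time`,
#'   `b_peak_time` (ms post-flash) and `a_flagged` (no negative deflection).
#' @export
measure_erg_waves <- function(trace, a_window = c(0.005, 0.080),
                              b_window = c(0.020, 0.300),
                              b_from = c("trough", "baseline")) {
  stopifnot(inherits(trace, "rod_trace"), trace$kind == "erg_voltage")
  b_from <- match.arg(b_from)
  base <- trace_baseline(trace, window_s = 0.02)
  fs <- trace$sampling_rate
  post <- trace$samples[trace$t0:length(trace$samples)] - base
  win_idx <- function(w) {
    i <- (round(w[1] * fs) + 1L):min(round(w[2] * fs) + 1L, length(post))
    i[i >= 1]
  }
  ia <- win_idx(a_window); ib <- win_idx(b_window)
  a_i <- ia[which.min(post[ia])]
  b_i <- ib[which.max(post[ib])]
  a_amp <- max(0, -post[a_i])
  a_flagged <- -post[a_i] <= 0
  if (a_flagged) warning("no negative a-wave deflection; a-amplitude flagged 0")
  trough_val <- post[a_i]
  b_amp <- if (b_from == "trough") post[b_i] - trough_val else max(0, post[b_i])
  a_t <- (a_i - 1) / fs * 1000
  b_t <- (b_i - 1) / fs * 1000
  if (!a_flagged && a_t >= b_t)
    stop("a-trough does not precede b-peak: inverted-polarity trace rejected")
  list(a_amplitude = a_amp, b_amplitude = b_amp,
       a_trough_time = a_t, b_peak_time = b_t, a_flagged = a_flagged)
}

#' Fit ERG a- and b-wave intensity-response relations
#'
#' Measures both wave amplitudes at every flash strength of the series and
#' fits each wave's (strength, amplitude) relation with the Hill equation,
#' yielding the sensitivity I_0.5 (cd.s/m2) and V_max (uV) per wave.
#'
#' @param series An `erg_series` (see [generate_erg_series()]): `strengths`,
#'   `traces`, `metadata`. At least 5 strengths spanning the dynamic range.
#' @param ... Passed to [measure_erg_waves()].
#' @return A list of class `erg_sensitivity` with `a` and `b` ([fit_hill()]
#'   objects) and the measured `amplitudes` data frame.
#' @export
fit_erg_sensitivity <- function(series, ...) {
  stopifnot(inherits(series, "erg_series"), length(series$strengths) >= 5)
  meas <- lapply(series$traces, measure_erg_waves, ...)
  amp <- data.frame(strength = series$strengths,
                    a = vapply(meas, `[[`, numeric(1), "a_amplitude"),
                    b = vapply(meas, `[[`, numeric(1), "b_amplitude"))
  structure(list(a = fit_hill(amp$strength, amp$a),
                 b = fit_hill(amp$strength, amp$b),
                 amplitudes = amp),
            class = "erg_sensitivity")
}

#' @export
print.erg_sensitivity <- function(x, ...) {
  cat(sprintf("<erg_sensitivity> a-wave: I_0.5 %.3g cd.s/m2, V_max %.4g uV | b-wave: I_0.5 %.3g, V_max %.4g\n",
              x$a$I_half, x$a$R_max, x$b$I_half, x$b$R_max))
  invisible(x)
}
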