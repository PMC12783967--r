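#' Sampled recording trace
#'
#' Container for a uniformly sampled current or voltage recording together
#' with the acquisition metadata the analyses need: sampling rate, the
#' low-pass cutoff applied at acquisition, the index of stimulus onset and
#' the kind of signal.
#'
#' @param samples Numeric vector of sampled values (pA for currents, uV for
#'   ERG voltages).
#' @param sampling_rate Sampling rate in Hz.
#' @param lowpass_cutoff Acquisition low-pass filter cutoff in Hz; must be
#'   below the Nyquist frequency.
#' @param t0 Index of stimulus onset (1-based); `NA` for recordings without
#'   a stimulus (e.g. dark epochs).
#' @param kind One of `"rod_current"`, `"rbc_current"`, `"erg_voltage"`.
#' @param unit Unit string, `"pA"` or `"uV"`.
#'
#' @return An object of class `rod_trace`: a list with the fields above.
#' @examples
#' tr <- rod_trace(sin(seq(0, 1, by = 1e-3)), sampling_rate = 1000,
#'                 lowpass_cutoff = 300, t0 = 100, kind = "rod_current")
#' trace_time(tr)[1:5]
#' @export
rod_trace <- function(samples, sampling_rate, lowpass_cutoff = sampling_rate / 4,
                      t0 = NA_integer_, kind = c("rod_current", "rbc_current",
                                                 "erg_voltage"),
                      unit = if (match.arg(kind) == "erg_voltage") "uV" else "pA") {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  sampling_rate <- as.numeric(sampling_rate)
  stopifnot(length(samples) >= 2, is.finite(sampling_rate), sampling_rate > 0)
  if (!is.finite(lowpass_cutoff) || lowpass_cutoff <= 0 ||
      lowpass_cutoff >= sampling_rate / 2)
    stop("lowpass_cutoff must lie in (0, sampling_rate/2)")
  if (!is.na(t0)) {
    t0 <- as.integer(t0)
    if (t0 < 1L || t0 > length(samples))
      stop("t0 must index into the trace")
  }
  if (!unit %in% c("pA", "uV"))
    stop("unit must be 'pA' or 'uV'")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 lowpass_cutoff = lowpass_cutoff, t0 = t0, kind = kind,
                 unit = unit),
            class = "rod_trace")
}

#' @export
print.rod_trace <- function(x, ...) {
  cat(sprintf("<rod_trace> %s, %d samples @ %g Hz (%.3g s), LP %g Hz",
              x$kind, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$lowpass_cutoff))
  if (!is.na(x$t0))
    cat(sprintf(", stimulus at %.4g s", (x$t0 - 1) / x$sampling_rate))
  cat("\n")
  invisible(x)
}

#' Time axis of a trace
#'
#' @param trace A [rod_trace()].
#' @param relative If `TRUE` (default) time is measured from stimulus onset
#'   (when `t0` is set), otherwise from the first sample.
#' @return Numeric vector of times in seconds, one per sample.
#' @export
trace_time <- function(trace, relative = TRUE) {
  t <- (seq_along(trace$samples) - 1) / trace$sampling_rate
  if (relative && !is.na(trace$t0)) t <- t - (trace$t0 - 1) / trace$sampling_rate
  t
}

# mean of the pre-stimulus window (last `window_s` seconds before t0)
trace_baseline <- function(trace, window_s = 0.05) {
  if (is.na(trace$t0)) stop("trace has no stimulus onset; baseline undefined")
  n <- round(window_s * trace$sampling_rate)
  if (trace$t0 - 1 < n)
    stop(sprintf("need >= %g ms of pre-stimulus baseline", window_s * 1000))
  mean(trace$samples[(trace$t0 - n):(trace$t0 - 1)])
}

#' Cell-level recording metadata
#'
#' Bookkeeping for a recorded cell: genotype, age group, holding potential,
#' junction-potential correction, resting membrane potential and capacitance.
#' The junction correction (-10 mV for the internal solution used here) is
#' recorded so it can be applied at most once per recording.
#'
#' @param genotype `"WT"` or `"GARP2KO"`.
#' @param age `"PM3"`, `"PM6"` or `"PM9"` (postnatal month).
#' @param holding_potential_mV Holding potential (voltage clamp), mV.
#' @param junction_correction_mV Junction-potential correction, mV.
#' @param V_m Resting membrane potential, mV (current clamp), or `NA`.
#' @param C_pF Cell capacitance, pF, or `NA`.
#' @return A list of class `cell_metadata`.
#' @export
cell_metadata <- function(genotype = c("WT", "GARP2KO"),
                          age = c("PM3", "PM6", "PM9"),
                          holding_potential_mV = -40,
                          junction_correction_mV = -10,
                          V_m = NA_real_, C_pF = NA_real_) {
  structure(list(genotype = match.arg(genotype), age = match.arg(age),
                 holding_potential_mV = holding_potential_mV,
                 junction_correction_mV = junction_correction_mV,
                 V_m = V_m, C_pF = C_pF),
            class = "cell_metadata")
}

#' Flash family for one cell
#'
#' An ordered set of averaged flash responses from a single cell, one trace
#' per flash strength, with strengths increasing flash-to-flash (a factor of
#' 2 in the standard protocol).
#'
#' @param stimuli Numeric vector of flash strengths (R*/rod for single-cell
#'   recordings, cd.s/m2 for ERG), strictly increasing.
#' @param responses List of [rod_trace()] objects, one per stimulus; all must
#'   share a sampling rate.
#' @param metadata A [cell_metadata()] object.
#' @return A list of class `flash_family`.
#' @export
flash_family <- function(stimuli, responses, metadata = cell_metadata()) {
  stopifnot(length(stimuli) == length(responses), length(stimuli) >= 1)
  if (any(stimuli <= 0)) stop("flash strengths must be positive")
  if (any(diff(stimuli) <= 0)) stop("flash strengths must be strictly increasing")
  fs <- vapply(responses, function(r) r$sampling_rate, numeric(1))
  if (length(unique(fs)) != 1L)
    stop("all responses must share one sampling rate")
  structure(list(stimuli = stimuli, responses = responses, metadata = metadata),
            class = "flash_family")
}

#' @export
print.flash_family <- function(x, ...) {
  cat(sprintf("<flash_family> %d flashes (%.3g-%.3g), %s %s\n",
              length(x$stimuli), min(x$stimuli), max(x$stimuli),
              x$metadata$genotype, x$metadata$age))
  invisible(x)
}
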