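# Default generating parameters for the six genotype x age cells. Values are
# the published group estimates for this strain pair: Hill sensitivity and
# amplitude rows of the rod response table, amplification constant and
# recovery time constant from the kinetics figure, band-limited dark-noise
# power from the noise row, ERG Vmax/I0.5 from the ERG table, and the
# outer-segment length distributions from the morphometry histograms.
.preset_table <- local({
  df <- expand.grid(age = c("PM3", "PM6", "PM9"),
                    label = c("WT", "GARP2KO"),
                    stringsAsFactors = FALSE)[, 2:1]
  df$I_half   <- c(20.8, 21.4, 24.0, 16.5, 21.7, 27.3)   # R*/rod
  df$R_max    <- c(23.4, 24.8, 27.0, 26.8, 22.3, 24.7)   # pA
  df$hill_n   <- c(1.3, 1.4, 1.3, 1.3, 1.4, 1.1)
  df$gain_A   <- c(3.8, 3.8, 3.8, 3.9, 3.9, 3.9)         # s^-2
  df$tau_rec  <- c(251, 251, 251, 233, 233, 233)         # ms
  df$cellular_band_power <- c(0.17, 0.20, 0.18, 0.07, 0.09, 0.17)  # pA^2
  df$erg_a_ihalf <- c(1.7, 1.1, 1.5, 2.0, 1.0, 1.5)      # cd s/m2
  df$erg_a_vmax  <- c(270, 282, 236, 246, 284, 170)      # uV
  df$erg_b_ihalf <- c(0.03, 0.01, 0.03, 0.03, 0.01, 0.03)
  df$erg_b_vmax  <- c(516, 505, 396, 447, 488, 313)
  df
})

#' Genotype/age generating preset
#'
#' Returns the default generating parameters for one genotype x age cohort:
#' Hill sensitivity (`I_half`, `hill_n`, `R_max`), Lamb-Pugh amplification
#' constant `gain_A` and activation delay `t_delay`, dim-flash recovery time
#' constant `tau_rec`, the target band-limited (0.6-10 Hz) cellular
#' dark-noise power, the instrumental white-noise SD, the outer-segment
#' length Gaussian mixture, and the ERG a-/b-wave Hill parameters. These are
#' the cohort-level estimates for this wild-type/knockout strain pair and
#' are the ground truth the synthetic generator encodes.
#'
#' @param label `"WT"` or `"GARP2KO"`.
#' @param age `"PM3"`, `"PM6"` or `"PM9"`.
#' @param ... Named overrides of any preset field.
#' @return A list of class `genotype_preset` with fields `label`, `age`,
#'   `gain_A` (s^-2), `t_delay` (s), `R_max` (pA), `I_half` (R*/rod),
#'   `hill_n`, `tau_rec` (ms), `cellular_band_power` (pA^2),
#'   `instrument_sd` (pA), `ros_mixture` (data frame mean/fwhm/weight, um),
#'   `erg_a_vmax`/`erg_b_vmax` (uV), `erg_a_ihalf`/`erg_b_ihalf` (cd.s/m2),
#'   `erg_hill_n`.
#' @examples
#' genotype_preset("WT", "PM3")$I_half
#' @export
genotype_preset <- function(label = c("WT", "GARP2KO"),
                            age = c("PM3", "PM6", "PM9"), ...) {
  label <- match.arg(label)
  age <- match.arg(age)
  row <- .preset_table[.preset_table$label == label & .preset_table$age == age, ]
  ros <- if (label == "WT") {
    data.frame(mean = 27.5, fwhm = 6.3, weight = 1)
  } else {
    data.frame(mean = c(26.8, 34.0), fwhm = c(7.2, 7.0), weight = c(0.77, 0.23))
  }
  p <- list(label = label, age = age,
            gain_A = row$gain_A, t_delay = 0.003, R_max = row$R_max,
            I_half = row$I_half, hill_n = row$hill_n, tau_rec = row$tau_rec,
            cellular_band_power = row$cellular_band_power,
            instrument_sd = 1.0, ros_mixture = ros,
            erg_a_vmax = row$erg_a_vmax, erg_a_ihalf = row$erg_a_ihalf,
            erg_b_vmax = row$erg_b_vmax, erg_b_ihalf = row$erg_b_ihalf,
            erg_hill_n = 1.0)
  over <- list(...)
  p[names(over)] <- over
  validate_preset(structure(p, class = "genotype_preset"))
}

validate_preset <- function(p) {
  pos <- c("gain_A", "R_max", "I_half", "hill_n", "tau_rec", "instrument_sd",
           "erg_a_vmax", "erg_a_ihalf", "erg_b_vmax", "erg_b_ihalf",
           "erg_hill_n")
  for (f in pos)
    if (!is.finite(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("preset field '%s' must be a positive number", f))
  if (p$hill_n < 0.5) stop("hill_n must be >= 0.5")
  if (p$t_delay < 0 || p$t_delay > 0.02)
    stop("t_delay must lie in [0, 20 ms]")
  if (p$cellular_band_power < 0)
    stop("cellular_band_power must be non-negative")
  m <- p$ros_mixture
  if (any(m$fwhm <= 0)) stop("ros_mixture FWHM must be positive")
  if (abs(sum(m$weight) - 1) > 1e-8) stop("ros_mixture weights must sum to 1")
  p
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf(paste0("<genotype_preset> %s %s: I_half %.3g R*/rod, n %.2g, ",
                     "R_max %.3g pA, A %.2g s^-2, tau_rec %g ms, ",
                     "band power %.3g pA^2\n"),
              x$label, x$age, x$I_half, x$hill_n, x$R_max, x$gain_A,
              x$tau_rec, x$cellular_band_power))
  invisible(x)
}

#' Simulation configuration
#'
#' Acquisition and protocol settings for the synthetic generator. Defaults
#' mirror the recording conditions: single-cell currents sampled at 10 kHz
#' and low-pass filtered at 300 Hz, flash strengths doubling flash-to-flash,
#' 200 ms of pre-stimulus baseline, and a post-stimulus window long enough
#' to cover activation plus five recovery time constants.
#'
#' @param sampling_rate Hz.
#' @param duration Post-stimulus duration, s.
#' @param pre_stimulus Pre-stimulus baseline duration, s.
#' @param flash_ladder Flash strengths, strictly increasing; the default
#'   doubles from 2 to 256 R*/rod.
#' @param lowpass_cutoff Acquisition low-pass cutoff, Hz.
#' @param noise_sd Additive recording noise SD (pA), applied after low-pass
#'   shaping.
#' @param seed Integer master seed.
#' @param n_cells Number of cells for multi-cell simulations.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 1e4, duration = 1.5,
                              pre_stimulus = 0.2,
                              flash_ladder = 2 * 2^(0:7),
                              lowpass_cutoff = 300, noise_sd = 0.3,
                              seed = 1L, n_cells = 1L) {
  stopifnot(sampling_rate > 0, duration > 0, pre_stimulus >= 0.05,
            length(flash_ladder) >= 1, noise_sd >= 0, n_cells >= 1)
  if (any(flash_ladder <= 0)) stop("flash strengths must be positive")
  if (any(diff(flash_ladder) <= 0)) stop("flash_ladder must be strictly increasing")
  if (lowpass_cutoff >= sampling_rate / 2)
    stop("lowpass_cutoff must be below Nyquist")
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 pre_stimulus = pre_stimulus, flash_ladder = flash_ladder,
                 lowpass_cutoff = lowpass_cutoff, noise_sd = noise_sd,
                 seed = as.integer(seed), n_cells = as.integer(n_cells)),
            class = "simulation_config")
}
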