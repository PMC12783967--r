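# Per-cell photoresponse metrics and model fits: response amplitude and
# time-to-peak, the Hill intensity-response fit, the joint ("ensemble")
# Lamb-Pugh fit of flash-family leading edges, and the dim-flash recovery
# time constant.

#' Lamb-Pugh activation model
#'
#' Rising phase of the rod flash response during phototransduction
#' activation: R(t) = R_max (1 - exp(-0.5 Phi A (t - t_delay)^2)), zero for
#' `t <= t_delay`. `A` is the amplification constant (s^-2), `Phi` the
#' number of photoisomerizations per rod for the flash.
#'
#' @param t Time since stimulus onset, s (vectorised).
#' @param phi Photoisomerizations per rod.
#' @param A Amplification constant, s^-2.
#' @param t_delay Activation delay, s.
#' @param R_max Saturating amplitude.
#' @return Model response at `t`.
#' @examples
#' lamb_pugh_model(0.1, phi = 20, A = 3.8)  # 1 - exp(-0.38)
#' @export
lamb_pugh_model <- function(t, phi, A, t_delay = 0, R_max = 1)
  R_max * (1 - exp(-0.5 * phi * A * pmax(t - t_delay, 0)^2))

#' Peak amplitude and time-to-peak of a flash response
#'
#' Baseline (mean of the pre-stimulus window) is subtracted, and the
#' response extremum is located after stimulus onset. `I_max` is the
#' magnitude of that extremum; `T_peak` is the time from stimulus onset to
#' it, in ms. Ties in the extremum are broken by the earliest sample.
#'
#' @param trace A [rod_trace()] with `t0` set and at least 50 ms of
#'   pre-stimulus baseline.
#' @param baseline_window Length of the pre-stimulus baseline window, s.
#' @return A list with `I_max` (pA or uV), `T_peak` (ms; `NA` and
#'   `flat = TRUE` for an all-flat trace) and `baseline`.
#' @export
measure_flash_metrics <- function(trace, baseline_window = 0.05) {
  stopifnot(inherits(trace, "rod_trace"))
  base <- trace_baseline(trace, baseline_window)
  post <- trace$samples[trace$t0:length(trace$samples)] - base
  if (all(abs(post) < .Machine$double.eps^0.5)) {
    warning("flat trace: I_max = 0, T_peak undefined")
    return(list(I_max = 0, T_peak = NA_real_, baseline = base, flat = TRUE))
  }
  i <- which.max(abs(post))  # which.max takes the earliest of tied extrema
  list(I_max = abs(post[i]),
       T_peak = (i - 1) / trace$sampling_rate * 1000,
       baseline = base, flat = FALSE)
}

#' Hill intensity-response model
#'
#' Fraction of the maximal response at flash strength `I`:
#' R/R_max = I^n / (I^n + I_half^n). Strictly increasing in `I`, 0 at
#' `I = 0`, 1/2 at `I = I_half`, approaching 1 as `I` grows.
#'
#' @param I Flash strength(s), >= 0.
#' @param fit A list (or `hill_fit`) with `I_half` and `hill_n`.
#' @return Fraction(s) of `R_max` in `[0, 1)`.
#' @examples
#' hill_model(20.8, list(I_half = 20.8, hill_n = 1.3))  # 0.5
#' @export
hill_model <- function(I, fit) {
  stopifnot(all(I >= 0))
  .hill_fraction(I, fit$I_half, fit$hill_n)
}

#' Fit the Hill equation to an intensity-response curve
#'
#' Least-squares fit of R = R_max I^n / (I^n + I_half^n) to
#' (strength, amplitude) pairs, as used to estimate sensitivity (I_0.5).
#' The fit is flagged unreliable when the data do not span the half-maximal
#' point (fitted `I_half` outside the sampled strength range) and degenerate
#' when the amplitudes carry no information on the slope.
#'
#' @param strengths Flash strengths (> 0), length >= 4.
#' @param amplitudes Response amplitudes (same length, >= 0).
#' @return A list of class `hill_fit`: `I_half`, `hill_n`, `R_max`,
#'   `residual_norm`, `reliable`, `degenerate`.
#' @examples
#' s <- 2 * 2^(0:7)
#' a <- 23.4 * hill_model(s, list(I_half = 20.8, hill_n = 1.3))
#' fit_hill(s, a)
#' @export
fit_hill <- function(strengths, amplitudes) {
  stopifnot(length(strengths) == length(amplitudes), length(strengths) >= 4,
            all(strengths > 0))
  df <- data.frame(I = strengths, R = amplitudes)
  degenerate <- stats::sd(amplitudes) < 1e-12 * max(abs(amplitudes), 1)
  if (degenerate) {
    warning("degenerate intensity-response data: amplitudes carry no slope information")
    return(structure(list(I_half = NA_real_, hill_n = NA_real_,
                          R_max = mean(amplitudes), residual_norm = 0,
                          reliable = FALSE, degenerate = TRUE),
                     class = "hill_fit"))
  }
  r_max0 <- max(amplitudes)
  i_half0 <- strengths[which.min(abs(amplitudes - r_max0 / 2))]
  fit <- minpack.lm::nlsLM(R ~ R_max * I^n / (I^n + I_half^n), data = df,
                           start = list(R_max = r_max0, I_half = i_half0, n = 1),
                           lower = c(1e-12, 1e-12, 0.1), upper = c(Inf, Inf, 10),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  reliable <- p[["I_half"]] >= min(strengths) && p[["I_half"]] <= max(strengths)
  if (!reliable)
    warning("fitted I_half lies outside the sampled strength range; fit unreliable")
  structure(list(I_half = unname(p[["I_half"]]), hill_n = unname(p[["n"]]),
                 R_max = unname(p[["R_max"]]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 reliable = reliable, degenerate = FALSE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> I_half %.4g, n %.3g, R_max %.4g (resid %.3g%s)\n",
              x$I_half, x$hill_n, x$R_max, x$residual_norm,
              if (!x$reliable) ", UNRELIABLE" else ""))
  invisible(x)
}

# baseline-subtracted response magnitude over the post-stimulus window
.response_magnitude <- function(trace) {
  base <- trace_baseline(trace)
  abs(trace$samples[trace$t0:length(trace$samples)] - base)
}

#' Ensemble Lamb-Pugh fit of flash-family leading edges
#'
#' Fits the activation model R(t) = R_max (1 - exp(-0.5 Phi A (t -
#' t_delay)^2)) jointly across all flashes of a family, sharing a single
#' amplification constant `A` (s^-2) and delay `t_delay`. Each flash
#' contributes its leading-edge window only: from stimulus onset until the
#' response first reaches `edge_fraction` of its own peak, capped at
#' `edge_max_s` post-flash, which confines the fit to the
#' activation-dominated phase. Responses are baseline-subtracted and
#' normalised by `r_max` (by default the `R_max` of a Hill fit to the
#' family's peak amplitudes).
#'
#' @param family A [flash_family()]; stimuli are taken as Phi (R*/rod).
#' @param phi_list Photoisomerizations per flash; defaults to
#'   `family$stimuli`.
#' @param r_max Saturating amplitude used for normalisation; `NULL` fits it
#'   from the family's Hill relation.
#' @param edge_fraction Fraction of each flash's own peak ending its window.
#' @param edge_max_s Hard cap on the window length, s.
#' @param fix_t_delay If non-`NULL`, `t_delay` (s) is held at this value and
#'   only `A` is fitted.
#' @return A list of class `lamb_pugh_fit`: `A` (s^-2), `t_delay` (s),
#'   `R_max` (pA), `phi_list`, `fit_windows` (s, per flash),
#'   `residual_norm`, `per_flash_rss`.
#' @export
fit_lamb_pugh_ensemble <- function(family, phi_list = family$stimuli,
                                   r_max = NULL, edge_fraction = 0.5,
                                   edge_max_s = 0.08, fix_t_delay = NULL) {
  stopifnot(inherits(family, "flash_family"),
            length(phi_list) == length(family$stimuli))
  peaks <- vapply(family$responses,
                  function(tr) measure_flash_metrics(tr)$I_max, numeric(1))
  if (is.null(r_max))
    r_max <- fit_hill(family$stimuli, peaks)$R_max
  if (max(peaks) < 0.2 * r_max)
    stop("no flash reaches 20% of R_max: insufficient activation signal")
  fs <- family$responses[[1]]$sampling_rate
  windows <- lapply(seq_along(phi_list), function(i) {
    m <- .response_magnitude(family$responses[[i]])
    i_half <- which(m >= edge_fraction * peaks[i])[1]
    i_end <- min(i_half, round(edge_max_s * fs) + 1L, na.rm = TRUE)
    t <- (seq_len(i_end) - 1) / fs
    list(t = t, y = m[seq_len(i_end)] / r_max, phi = phi_list[i])
  })
  t_all <- unlist(lapply(windows, `[[`, "t"))
  y_all <- unlist(lapply(windows, `[[`, "y"))
  phi_all <- unlist(lapply(windows, function(w) rep(w$phi, length(w$t))))
  model <- function(A, td) lamb_pugh_model(t_all, phi_all, A, td)
  # start A from the quadratic onset of the window ends
  a0 <- stats::median(vapply(windows, function(w) {
    k <- length(w$t)
    2 * w$y[k] / (w$phi * max(w$t[k], 1 / fs)^2)
  }, numeric(1)))
  if (!is.finite(a0) || a0 <= 0) a0 <- 1
  if (is.null(fix_t_delay)) {
    res <- minpack.lm::nls.lm(par = c(A = a0, td = 0.003),
                              fn = function(p) y_all - model(p[1], p[2]),
                              lower = c(1e-8, 0), upper = c(Inf, 0.02))
    A <- res$par[["A"]]; td <- res$par[["td"]]
  } else {
    res <- minpack.lm::nls.lm(par = c(A = a0),
                              fn = function(p) y_all - model(p[1], fix_t_delay),
                              lower = 1e-8)
    A <- res$par[["A"]]; td <- fix_t_delay
  }
  resid <- y_all - model(A, td)
  rss_by_flash <- tapply(resid^2, rep(seq_along(windows),
                                      vapply(windows, function(w) length(w$t),
                                             integer(1))), sum)
  structure(list(A = A, t_delay = td, R_max = r_max, phi_list = phi_list,
                 fit_windows = vapply(windows, function(w) max(w$t), numeric(1)),
                 residual_norm = sqrt(sum(resid^2)),
                 per_flash_rss = as.numeric(rss_by_flash)),
            class = "lamb_pugh_fit")
}

#' @export
print.lamb_pugh_fit <- function(x, ...) {
  cat(sprintf("<lamb_pugh_fit> A %.3g s^-2, t_delay %.3g ms, R_max %.3g (resid %.3g)\n",
              x$A, x$t_delay * 1000, x$R_max, x$residual_norm))
  invisible(x)
}

#' Average the dim-flash responses of a family
#'
#' A flash is "dim" when its peak amplitude is at most `dim_threshold` of
#' the saturating amplitude, keeping the response in the quasi-linear range.
#' Qualifying responses are baseline-subtracted and averaged pointwise
#' (native sign preserved).
#'
#' @param family A [flash_family()].
#' @param r_max Saturating amplitude; `NULL` takes the `R_max` of a Hill fit
#'   to the family's peaks.
#' @param dim_threshold Dim criterion as a fraction of `r_max`.
#' @return A [rod_trace()] (baseline-subtracted mean dim response).
#' @export
average_dim_flash_response <- function(family, r_max = NULL,
                                       dim_threshold = 0.2) {
  stopifnot(inherits(family, "flash_family"))
  peaks <- vapply(family$responses,
                  function(tr) measure_flash_metrics(tr)$I_max, numeric(1))
  if (is.null(r_max)) r_max <- fit_hill(family$stimuli, peaks)$R_max
  dim_idx <- which(peaks <= dim_threshold * r_max)
  if (length(dim_idx) == 0)
    stop("no flash qualifies as dim (peak <= dim_threshold * R_max)")
  mats <- vapply(dim_idx, function(i) {
    tr <- family$responses[[i]]
    tr$samples - trace_baseline(tr)
  }, numeric(length(family$responses[[1]]$samples)))
  tmpl <- family$responses[[dim_idx[1]]]
  rod_trace(rowMeans(mats), tmpl$sampling_rate, tmpl$lowpass_cutoff,
            t0 = tmpl$t0, kind = tmpl$kind)
}

#' Recovery time constant of a dim-flash response
#'
#' Fits a single exponential a exp(-t/tau) to the final portion of the
#' recovery: the samples from the time the response has fallen to
#' `tail_fraction` (default 35%) of its peak until it returns to baseline
#' (2% of peak) or the trace ends. The fit is seeded by a log-linear
#' regression and refined by nonlinear least squares.
#'
#' @param trace A [rod_trace()] containing a sub-saturating (dim) flash
#'   response whose peak has already passed.
#' @param tail_fraction Fraction of the peak at which the tail fit starts.
#' @param r_max Optional saturating amplitude; when given, the response must
#'   be dim (peak < 20% of `r_max`).
#' @return A list of class `recovery_fit`: `tau_rec` (ms),
#'   `fit_start_index`, `amplitude_at_start`, `n_points`.
#' @export
fit_recovery_tau <- function(trace, tail_fraction = 0.35, r_max = NULL) {
  stopifnot(inherits(trace, "rod_trace"))
  m <- .response_magnitude(trace)
  peak_i <- which.max(m)
  peak <- m[peak_i]
  if (!is.null(r_max) && peak >= 0.2 * r_max)
    stop("response is not dim (peak >= 20% of R_max)")
  after <- m[peak_i:length(m)]
  start_rel <- which(after <= tail_fraction * peak)[1]
  if (is.na(start_rel))
    stop(sprintf("recovery never falls below %.0f%% of peak within the trace",
                 100 * tail_fraction))
  end_rel <- which(after <= 0.02 * peak)[1]
  if (is.na(end_rel) || end_rel <= start_rel + 5L) end_rel <- length(after)
  idx <- start_rel:end_rel
  fs <- trace$sampling_rate
  t <- (idx - idx[1]) / fs
  y <- after[idx]
  pos <- y > 0.01 * peak
  lf <- stats::lm(log(y[pos]) ~ t[pos])
  tau0 <- -1 / stats::coef(lf)[[2]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 3
  fit <- minpack.lm::nlsLM(y ~ a * exp(-t / tau), data = data.frame(t = t, y = y),
                           start = list(a = y[1], tau = tau0),
                           lower = c(0, 1e-6))
  p <- stats::coef(fit)
  structure(list(tau_rec = unname(p[["tau"]]) * 1000,
                 fit_start_index = peak_i + start_rel - 1L +
                   (trace$t0 - 1L),
                 amplitude_at_start = y[1], n_points = length(idx)),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> tau_rec %.4g ms (%d points from index %d)\n",
              x$tau_rec, x$n_points, x$fit_start_index))
  invisible(x)
}
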