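# Shared fixtures and small independent oracles used across test files.

# trace with a smooth raised-cosine peak of known magnitude and latency,
# sitting on a flat baseline; negative-going like a photocurrent
peak_trace <- function(peak = 24, t_peak_ms = 143, fs = 1e4, pre = 0.1,
                       post = 0.6, width_ms = 120, offset = 0) {
  t <- (seq_len(round(post * fs)) - 1) / fs * 1000
  lobe <- ifelse(abs(t - t_peak_ms) <= width_ms / 2,
                 0.5 * (1 + cos(2 * pi * (t - t_peak_ms) / width_ms)), 0)
  rod_trace(c(numeric(round(pre * fs)), -peak * lobe) + offset,
            sampling_rate = fs, lowpass_cutoff = 300,
            t0 = round(pre * fs) + 1L, kind = "rod_current")
}

# dim-flash-like trace: raised-cosine rise to `peak`, then exponential
# recovery with time constant tau_ms, plus optional white noise
dim_flash_trace <- function(peak = 2, tau_ms = 251, fs = 1e4, pre = 0.1,
                            post = 2.0, rise_ms = 100, noise_sd = 0,
                            seed = 1) {
  t <- (seq_len(round(post * fs)) - 1) / fs * 1000
  rise <- ifelse(t < rise_ms, 0.5 * (1 - cos(pi * t / rise_ms)), NA)
  rec <- exp(-(t - rise_ms) / tau_ms)
  y <- peak * ifelse(t < rise_ms, rise, rec)
  y <- c(numeric(round(pre * fs)), -y)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), sd = noise_sd)
  }
  rod_trace(y, fs, lowpass_cutoff = 300, t0 = round(pre * fs) + 1L,
            kind = "rod_current")
}

# hand/rank-formula Kruskal-Wallis H (no ties), independent of kruskal.test
kw_hand <- function(groups) {
  values <- unlist(groups)
  r <- rank(values)
  n <- length(values)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  rbar <- tapply(r, idx, mean)
  ni <- tapply(r, idx, length)
  12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
}

# brute-force numeric tail probability of a two-component Gaussian mixture
mixture_tail_numeric <- function(cut, means, fwhms, weights) {
  dens <- function(x)
    weights[1] * dnorm(x, means[1], fwhm_to_sd(fwhms[1])) +
    weights[2] * dnorm(x, means[2], fwhm_to_sd(fwhms[2]))
  integrate(dens, cut, Inf, rel.tol = 1e-10)$value
}
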