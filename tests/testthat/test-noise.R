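# Welch PSD estimation, spectral subtraction and band-power integration.

white_trace <- function(sd, dur = 20, fs = 1000, seed = 1) {
  set.seed(seed)
  rod_trace(rnorm(dur * fs, sd = sd), fs, lowpass_cutoff = fs / 4,
            kind = "rod_current")
}

test_that("white-noise density is flat at sigma^2 / F_nyquist", {
  sd <- 1.3; fs <- 1000
  psds <- lapply(1:50, function(s) estimate_psd(white_trace(sd, fs = fs,
                                                            seed = s)))
  dens <- rowMeans(vapply(psds, `[[`, numeric(length(psds[[1]]$density)),
                          "density"))
  expect_lt(abs(mean(dens) / (sd^2 / (fs / 2)) - 1), 0.02)
  # flat: no frequency trend beyond Monte-Carlo noise
  expect_lt(abs(mean(dens[1:100]) / mean(dens[2301:2400]) - 1), 0.05)
  bp <- mean(vapply(psds, band_power, numeric(1)))
  expect_lt(abs(bp / (sd^2 * 9.4 / (fs / 2)) - 1), 0.05)
})

test_that("Parseval holds for every estimate and a pure tone integrates to a^2/2", {
  fs <- 1000
  set.seed(9)
  x <- rnorm(20 * fs)
  psd <- estimate_psd(rod_trace(x, fs, fs / 4, kind = "rod_current"))
  expect_lt(abs(sum(psd$density) * psd$delta_f / var(x) - 1), 0.05)
  a <- 2.5
  tone <- rod_trace(a * sin(2 * pi * 5 * (0:(20 * fs - 1)) / fs), fs, fs / 4,
                    kind = "rod_current")
  pt <- estimate_psd(tone)
  expect_equal(sum(pt$density) * pt$delta_f, a^2 / 2, tolerance = 0.02)
  zero <- rod_trace(numeric(20 * fs), fs, fs / 4, kind = "rod_current")
  expect_equal(max(abs(estimate_psd(zero)$density)), 0)
  expect_error(estimate_psd(white_trace(1, dur = 5), segment_length = 2),
               "0.6 Hz")
  expect_error(estimate_psd(white_trace(1, dur = 8), segment_length = 5),
               "2 segments")
})

test_that("spectral subtraction is pointwise and grid-checked", {
  p1 <- estimate_psd(white_trace(1, seed = 1))
  expect_equal(max(abs(subtract_instrumental(p1, p1)$density)), 0)
  zero <- p1; zero$density <- numeric(length(p1$density))
  expect_equal(subtract_instrumental(p1, zero)$density, p1$density)
  p_short <- estimate_psd(white_trace(1, seed = 2), segment_length = 4)
  expect_error(subtract_instrumental(p1, p_short), "grids differ")
  # E[total - instrumental] for independent white sources is the flat
  # density of the cellular variance alone
  s1 <- 0.8; s2 <- 1.1
  diffs <- vapply(1:50, function(s) {
    tot <- estimate_psd(white_trace(sqrt(s1^2 + s2^2), dur = 10, seed = s))
    ins <- estimate_psd(white_trace(s2, dur = 10, seed = s + 1000))
    mean(subtract_instrumental(tot, ins)$density)
  }, numeric(1))
  expect_lt(abs(mean(diffs) / (s1^2 / 500) - 1), 0.05)
})

test_that("band power integrates a flat density to S0 * width", {
  psd <- structure(list(frequencies = seq(0.2, 500, by = 0.2),
                        density = rep(0.03, 2500),
                        n_segments_averaged = 1, delta_f = 0.2),
                   class = "power_spectrum")
  expect_equal(band_power(psd, 0.6, 10), 0.03 * 9.4, tolerance = 1e-12)
  psd$density[psd$frequencies > 0.5 & psd$frequencies < 11] <- 0
  expect_equal(band_power(psd, 0.6, 10), 0)
  expect_error(band_power(psd, 0.05, 10), "outside")
})

test_that("cumulative curve is monotone and ends at the band power", {
  psd <- estimate_psd(white_trace(1.7, seed = 4))
  curve <- cumulative_power_curve(psd, 0.6, 10)
  expect_true(all(diff(curve$cumulative_power) >= 0))
  expect_equal(curve$cumulative_power[nrow(curve)], band_power(psd, 0.6, 10))
  # flat density integrates to a straight line
  flat <- structure(list(frequencies = seq(0.2, 500, by = 0.2),
                         density = rep(1, 2500), n_segments_averaged = 1,
                         delta_f = 0.2), class = "power_spectrum")
  cf <- cumulative_power_curve(flat, 0.6, 10)
  expect_equal(cf$cumulative_power, cf$frequency - 0.6, tolerance = 1e-12)
})

test_that("full pipeline recovers the cellular band power without bias", {
  p <- genotype_preset("WT", "PM3")
  vals <- vapply(1:30, function(s)
    analyze_noise(generate_dark_recording(p, simulation_config(seed = s),
                                          dark_duration = 20,
                                          sat_duration = 10.5))$cumulative_power,
    numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  # small negative bias from per-segment detrending is tolerated: the mean
  # must sit within 3 SE + 10% of the generating value
  expect_lt(abs(mean(vals) - 0.17), 3 * se + 0.017)
  # null recording: recovered power indistinguishable from zero
  p0 <- genotype_preset("WT", "PM3", cellular_band_power = 0)
  nulls <- vapply(1:15, function(s)
    analyze_noise(generate_dark_recording(p0, simulation_config(seed = s),
                                          dark_duration = 20,
                                          sat_duration = 10.5))$cumulative_power,
    numeric(1))
  expect_lt(abs(mean(nulls)), 3 * sd(nulls) / sqrt(length(nulls)))
})

test_that("estimator settings shift the recovered band power by < 10%", {
  p <- genotype_preset("WT", "PM3")
  recs <- lapply(1:6, function(s)
    generate_dark_recording(p, simulation_config(seed = s),
                            dark_duration = 30))
  base <- mean(vapply(recs, function(r) analyze_noise(r)$cumulative_power,
                      numeric(1)))
  alt1 <- mean(vapply(recs, function(r)
    analyze_noise(r, segment_length = 4)$cumulative_power, numeric(1)))
  alt2 <- mean(vapply(recs, function(r)
    analyze_noise(r, overlap = 0)$cumulative_power, numeric(1)))
  expect_lt(abs(alt1 / base - 1), 0.10)
  expect_lt(abs(alt2 / base - 1), 0.10)
})
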