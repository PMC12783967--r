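# Synthetic-recording generator: model arithmetic, seed determinism,
# Hill consistency of generated peaks, noise calibration, mixture draws
# and ERG round trips.

test_that("Lamb-Pugh activation model matches direct arithmetic and limits", {
  expect_equal(lamb_pugh_model(0.1, phi = 20, A = 3.8), 1 - exp(-0.38))
  expect_equal(lamb_pugh_model(c(0, 0.002, 0.003), 20, 3.8, t_delay = 0.003),
               c(0, 0, 0))
  expect_equal(lamb_pugh_model(0.05, phi = 1e12, A = 3.8, R_max = 24), 24)
})

test_that("flash families are deterministic under seed and reject bad input", {
  p <- genotype_preset("WT", "PM3")
  cfg <- simulation_config(seed = 42)
  f1 <- generate_flash_family(p, cfg)
  f2 <- generate_flash_family(p, cfg)
  expect_identical(f1$responses[[3]]$samples, f2$responses[[3]]$samples)
  f3 <- generate_flash_family(p, cfg, cell_index = 2)
  expect_false(identical(f1$responses[[3]]$samples, f3$responses[[3]]$samples))
  expect_error(simulation_config(flash_ladder = c(-1, 2)), "positive")
  expect_error(simulation_config(flash_ladder = c(4, 2)), "increasing")
  expect_error(generate_flash_family(p, simulation_config(duration = 0.5)),
               "tau_rec")
})

test_that("noise-free generated peaks follow the preset Hill relation", {
  for (geno in c("WT", "GARP2KO")) {
    p <- genotype_preset(geno, "PM3")
    fam <- generate_flash_family(p, simulation_config(seed = 1, noise_sd = 0))
    peaks <- vapply(fam$responses,
                    function(tr) measure_flash_metrics(tr)$I_max, numeric(1))
    pred <- p$R_max * hill_model(fam$stimuli, p)
    expect_true(all(abs(peaks / pred - 1) < 0.05))
  }
})

test_that("cellular noise is Parseval-calibrated to the target band power", {
  target <- 0.17
  fs <- 1e4
  vals <- vapply(1:50, function(s) {
    set.seed(s)
    x <- rodnoise:::.shaped_cellular_noise(round(20 * fs), fs, target)
    band_power(estimate_psd(rod_trace(x, fs, 300, kind = "rod_current")))
  }, numeric(1))
  expect_lt(abs(mean(vals) / target - 1), 0.10)
})

test_that("zero cellular power gives dark and saturated epochs of equal variance", {
  p <- genotype_preset("WT", "PM3", cellular_band_power = 0)
  ratios <- vapply(1:10, function(s) {
    rec <- generate_dark_recording(p, simulation_config(seed = s),
                                   dark_duration = 20, sat_duration = 10.5)
    var(rec$dark_epoch$samples) / var(rec$saturated_epoch$samples)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.01)
  expect_error(generate_dark_recording(p, simulation_config(), dark_duration = 5),
               ">= 20 s")
})

test_that("doubling instrumental noise leaves recovered cellular power unchanged", {
  recover <- function(p, s)
    analyze_noise(generate_dark_recording(p, simulation_config(seed = s),
                                          dark_duration = 20,
                                          sat_duration = 10.5))$cumulative_power
  p1 <- genotype_preset("WT", "PM3")
  p2 <- genotype_preset("WT", "PM3", instrument_sd = 2)
  v1 <- vapply(1:25, recover, numeric(1), p = p1)
  v2 <- vapply(26:50, recover, numeric(1), p = p2)
  se <- sqrt(var(v1) / 25 + var(v2) / 25)
  expect_lt(abs(mean(v1) - mean(v2)), 3 * se)
})

test_that("outer segment length draws follow the preset mixture", {
  wt <- genotype_preset("WT", "PM3")
  x <- generate_ros_lengths(wt, 1e4, seed = 7)
  expect_lt(abs(mean(x) - 27.5), 0.2)
  expect_identical(x, generate_ros_lengths(wt, 1e4, seed = 7))
  # degenerate weight vector: no draws from the (far away) second component
  p0 <- genotype_preset("WT", "PM3",
                        ros_mixture = data.frame(mean = c(27.5, 500),
                                                 fwhm = c(6.3, 1),
                                                 weight = c(1, 0)))
  expect_true(all(generate_ros_lengths(p0, 5000, seed = 1) < 100))
  expect_error(genotype_preset("WT", "PM3",
                               ros_mixture = data.frame(mean = 27, fwhm = -1,
                                                        weight = 1)),
               "FWHM")
  # empirical tail fraction vs brute-force numeric CDF oracle
  ko <- genotype_preset("GARP2KO", "PM3")
  m <- ko$ros_mixture
  cut <- mean(m$mean)
  x <- generate_ros_lengths(ko, 1e5, seed = 11)
  expect_lt(abs(mean(x > cut) -
                  mixture_tail_numeric(cut, m$mean, m$fwhm, m$weight)),
            0.01)
})

test_that("ERG traces encode the Hill amplitudes and round-trip exactly", {
  p <- genotype_preset("WT", "PM3")
  w <- measure_erg_waves(generate_erg_trace(p, p$erg_a_ihalf))
  expect_equal(w$a_amplitude, p$erg_a_vmax / 2)
  w2 <- measure_erg_waves(generate_erg_trace(p, 120))
  expect_equal(w2$a_amplitude,
               p$erg_a_vmax * 120 / (120 + p$erg_a_ihalf), tolerance = 1e-12)
  expect_equal(w2$a_amplitude, 266.2, tolerance = 1e-3)  # ~ 270 uV V_max
  expect_equal(w2$b_amplitude,
               p$erg_b_vmax * 120 / (120 + p$erg_b_ihalf), tolerance = 1e-12)
  expect_lt(w2$a_trough_time, w2$b_peak_time)
  expect_error(generate_erg_trace(p, 500), "ladder")
  expect_error(generate_erg_trace(p, 0), "ladder")
})
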