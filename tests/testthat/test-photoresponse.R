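# Photoresponse metrics and model fits: peak measurement, Hill fit,
# ensemble Lamb-Pugh fit and recovery time constant.

test_that("flash metrics recover peak, latency and ignore offsets", {
  m <- measure_flash_metrics(peak_trace(peak = 24, t_peak_ms = 143))
  expect_equal(m$I_max, 24, tolerance = 1e-9)
  expect_equal(m$T_peak, 143, tolerance = 0.11)  # one sample at 10 kHz
  m2 <- measure_flash_metrics(peak_trace(peak = 24, t_peak_ms = 143,
                                         offset = -12.5))
  expect_equal(m2$I_max, m$I_max)
  expect_equal(m2$T_peak, m$T_peak)
  flat <- rod_trace(rep(3, 2000), 1e4, 300, t0 = 1000, kind = "rod_current")
  expect_warning(mf <- measure_flash_metrics(flat), "flat")
  expect_equal(mf$I_max, 0)
  expect_true(is.na(mf$T_peak))
})

test_that("Hill model obeys its bounds, midpoint and monotonicity", {
  fit <- list(I_half = 20.8, hill_n = 1.3)
  expect_equal(hill_model(20.8, fit), 0.5)
  expect_equal(hill_model(0, fit), 0)
  expect_equal(hill_model(2, list(I_half = 1, hill_n = 1)), 2 / 3)
  set.seed(5)
  for (i in 1:20) {
    f <- list(I_half = runif(1, 0.1, 100), hill_n = runif(1, 0.5, 4))
    I <- sort(runif(50, 0, 500))
    v <- hill_model(I, f)
    expect_true(all(v >= 0 & v < 1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("Hill fit round-trips noise-free parameters and flags bad data", {
  s <- 2 * 2^(0:7)
  truth <- list(I_half = 20.8, hill_n = 1.3)
  a <- 23.4 * hill_model(s, truth)
  fit <- fit_hill(s, a)
  expect_equal(fit$I_half, 20.8, tolerance = 5e-4)
  expect_equal(fit$hill_n, 1.3, tolerance = 5e-4)
  expect_equal(fit$R_max, 23.4, tolerance = 5e-4)
  # scaling strengths scales I_half, leaves n unchanged
  fit_k <- fit_hill(7 * s, a)
  expect_equal(fit_k$I_half, 7 * fit$I_half, tolerance = 1e-6)
  expect_equal(fit_k$hill_n, fit$hill_n, tolerance = 1e-6)
  expect_warning(d <- fit_hill(s, rep(11.7, 8)), "degenerate")
  expect_true(d$degenerate)
  # non-spanning data (all far below half-max) flagged unreliable
  expect_warning(u <- fit_hill(s / 1000, 23.4 * hill_model(s / 1000, truth)),
                 "unreliable")
  expect_false(u$reliable)
})

test_that("ensemble Lamb-Pugh fit is exact on noise-free families", {
  p <- genotype_preset("WT", "PM3")
  fam <- generate_flash_family(p, simulation_config(seed = 1, noise_sd = 0))
  fit <- fit_lamb_pugh_ensemble(fam)
  expect_equal(fit$A, 3.8, tolerance = 1e-3)
  expect_equal(fit$t_delay, 0.003, tolerance = 1e-3)
  expect_lt(fit$residual_norm, 1e-3)
  expect_true(all(fit$fit_windows <= 0.08 + 1e-9))
})

test_that("only the product Phi * A is identified", {
  p <- genotype_preset("WT", "PM3")
  fam <- generate_flash_family(p, simulation_config(seed = 2, noise_sd = 0))
  fit <- fit_lamb_pugh_ensemble(fam)
  fit_k <- fit_lamb_pugh_ensemble(fam, phi_list = 4 * fam$stimuli)
  expect_equal(fit_k$A, fit$A / 4, tolerance = 1e-4)
  expect_equal(fit_k$t_delay, fit$t_delay, tolerance = 1e-5)
})

test_that("ensemble fit is unbiased at generator default noise", {
  p <- genotype_preset("WT", "PM3")
  As <- vapply(1:50, function(s) {
    fam <- generate_flash_family(p, simulation_config(seed = s))
    fit_lamb_pugh_ensemble(fam)$A
  }, numeric(1))
  expect_lt(abs(mean(As) / 3.8 - 1), 0.05)
})

test_that("ensemble fit rejects families without activation signal", {
  p <- genotype_preset("WT", "PM3")
  cfg <- simulation_config(flash_ladder = c(0.25, 0.5, 1, 2), noise_sd = 0)
  expect_warning(fam <- generate_flash_family(p, cfg), "saturate")
  expect_error(fit_lamb_pugh_ensemble(fam, r_max = p$R_max),
               "insufficient activation")
})

test_that("recovery tau fit matches a pure exponential tail and rescales", {
  tr <- dim_flash_trace(peak = 2, tau_ms = 251)
  fit <- fit_recovery_tau(tr, r_max = 23.4)
  expect_lt(abs(fit$tau_rec / 251 - 1), 0.02)
  # stretching time by 2 doubles tau
  tr2 <- dim_flash_trace(peak = 2, tau_ms = 251)
  tr2$sampling_rate <- tr2$sampling_rate / 2
  fit2 <- fit_recovery_tau(tr2)
  expect_equal(fit2$tau_rec, 2 * fit$tau_rec, tolerance = 1e-6)
  # never dropping below 35% of peak is an error
  short <- dim_flash_trace(peak = 2, tau_ms = 5000, post = 0.5)
  expect_error(fit_recovery_tau(short), "never falls")
  # saturating response rejected when R_max known
  expect_error(fit_recovery_tau(dim_flash_trace(peak = 20), r_max = 23.4),
               "not dim")
})

test_that("recovery tau is robust to additive noise", {
  taus <- vapply(1:20, function(s)
    fit_recovery_tau(dim_flash_trace(peak = 2, tau_ms = 251,
                                     noise_sd = 0.2, seed = s))$tau_rec,
    numeric(1))
  expect_lt(abs(mean(taus) / 251 - 1), 0.10)
})

test_that("dim-flash averaging is linear and respects the dim criterion", {
  p <- genotype_preset("WT", "PM3")
  cfg <- simulation_config(seed = 3, noise_sd = 0)
  fam <- generate_flash_family(p, cfg)
  avg <- average_dim_flash_response(fam, r_max = p$R_max)
  # flashes 2 and 4 R*/rod are dim (<20% of R_max) for this preset
  d1 <- fam$responses[[1]]$samples - mean(fam$responses[[1]]$samples[1:2000])
  d2 <- fam$responses[[2]]$samples - mean(fam$responses[[2]]$samples[1:2000])
  expect_equal(avg$samples, (d1 + d2) / 2, tolerance = 1e-9)
  # single dim flash: returned unchanged
  one <- flash_family(fam$stimuli[1], fam$responses[1], fam$metadata)
  avg1 <- average_dim_flash_response(one, r_max = p$R_max)
  expect_equal(avg1$samples, d1, tolerance = 1e-9)
  # opposite-sign pair averages to zero
  tr <- fam$responses[[1]]
  neg <- rod_trace(-tr$samples, tr$sampling_rate, tr$lowpass_cutoff,
                   t0 = tr$t0, kind = tr$kind)
  pair <- flash_family(c(1, 2), list(tr, neg), fam$metadata)
  expect_equal(max(abs(average_dim_flash_response(pair, r_max = 1e6)$samples)),
               0, tolerance = 1e-9)
  expect_error(average_dim_flash_response(fam, r_max = 1e6,
                                          dim_threshold = 1e-9), "dim")
})
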