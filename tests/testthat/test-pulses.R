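test_that("configuration validation rejects unphysical parameters", {
  expect_error(raff2_config(f1max_hz = 0), "positive")
  expect_error(raff2_config(625, duration_s = -1), "positive")
  expect_error(raff2_config(625, n_samples = 8), ">= 16")
  expect_error(raff2_config(625, b1_scale = 0), "\\(0, 2\\]")
  expect_error(raff2_config(625, b1_scale = 2.5), "\\(0, 2\\]")
})

test_that("default duration convention gives the printed pulse length", {
  cfg <- raff2_config(625)
  expect_equal(cfg$duration_s, sqrt(2) / 625)
  expect_equal(round(cfg$duration_s * 1000, 2), 2.26)
})

test_that("waveform samples follow the sine/cosine AM-FM definition", {
  wf <- make_raff2_pulse(raff2_config(625, phi0 = 0, n_samples = 512))
  w1max <- 2 * pi * 625
  # at t = 0: amplitude sin(0) = 0, frequency offset cos(0) = 1
  expect_equal(wf$omega1[1], 0)
  expect_equal(wf$delta_omega[1], w1max)
  expect_true(all(wf$omega1 >= 0))
  expect_equal(wf$omega1, 1 * w1max * abs(sin(w1max * wf$t)))
  expect_equal(wf$phase[1], 0)
  # B1 scaling multiplies the AM only
  wf2 <- make_raff2_pulse(raff2_config(625, n_samples = 512,
                                       b1_scale = 0.4))
  expect_equal(wf2$omega1, 0.4 * wf$omega1)
  expect_equal(wf2$delta_omega, wf$delta_omega)
  expect_equal(wf2$phase, wf$phase)
})

test_that("integrated phase matches the closed form of the FM integral", {
  # phi(t) = sin(w1max t + phi0) - sin(phi0); the implementation integrates
  # numerically, the closed form is the independent check
  for (phi0 in c(0, 0.5, pi / 3)) {
    wf <- make_raff2_pulse(raff2_config(625, phi0 = phi0,
                                        n_samples = 1024))
    expected <- sin(2 * pi * 625 * wf$t + phi0) - sin(phi0)
    expect_lt(max(abs(wf$phase - expected)), 1e-6)
  }
  # for phi0 = 0 the phase modulation peaks at 1 rad
  wf0 <- make_raff2_pulse(raff2_config(625, phi0 = 0, n_samples = 2048))
  expect_equal(max(abs(wf0$phase)), 1, tolerance = 1e-4)
})

test_that("train arithmetic reproduces the protocol totals", {
  p <- make_raff2_pulse(raff2_config(625, duration_s = 2.26e-3))
  totals <- vapply(c(8L, 16L, 24L), function(n)
    assemble_prep_train(p, n, 0.7e-3)$total_duration_s * 1000, numeric(1))
  expect_equal(totals, c(22.98, 46.66, 70.34), tolerance = 1e-12)
  # single pulse: no spoiler contribution
  expect_equal(assemble_prep_train(p, 1, 0.7e-3)$total_duration_s,
               p$duration_s)
  expect_error(assemble_prep_train(p, 0), ">= 1")
  expect_error(assemble_prep_train(p, 2, -1e-3), "non-negative")
})

test_that("on-resonance effective field is stationary in both frames", {
  wf <- make_raff2_pulse(raff2_config(625, n_samples = 1e4))
  ft <- field_trajectory(wf, 0)
  # 1st frame: |Beff| = f1max, analytic identity sin^2 + cos^2 = 1
  expect_lt(diff(range(ft$b_eff_mag)) / 625, 1e-12)
  # 2nd frame: |E| = sqrt(2) f1max, sweep rate w1max
  expect_lt(max(abs(ft$e_field_mag - sqrt(2) * 625)) / (sqrt(2) * 625),
            1e-6)
  expect_lt(max(abs(ft$sweep_rate - 2 * pi * 625)) / (2 * pi * 625), 1e-6)
  # two full revolutions about E over the default duration
  expect_equal(2 * pi * mean(ft$e_field_mag) * wf$duration_s, 4 * pi,
               tolerance = 1e-9)
})

test_that("off-resonance modulates the effective field magnitude", {
  wf <- make_raff2_pulse(raff2_config(625, n_samples = 4096))
  ft <- field_trajectory(wf, 50)
  expect_gt(diff(range(ft$b_eff_mag)), 1)   # no longer constant
  # brute-force max over the dense grid: attained where FM = +625, AM = 0
  expect_equal(max(ft$b_eff_mag), 675, tolerance = 1e-9)
})

test_that("RF power fraction matches quadrature for AM shapes", {
  # constant-amplitude (continuous-wave) reference
  expect_equal(rf_power_fraction(cw_pulse(625, 2e-3, 512)), 1.0)
  # rectified sine over integer half-periods: exactly 1/2
  p_int <- make_raff2_pulse(raff2_config(625, duration_s = 2 / 625,
                                         n_samples = 4097))
  expect_equal(rf_power_fraction(p_int), 0.5, tolerance = 1e-6)
  # scaled amplitude, normalized to nominal peak: 0.4^2 * 1/2
  p_scaled <- make_raff2_pulse(raff2_config(625, duration_s = 2 / 625,
                                            n_samples = 4097,
                                            b1_scale = 0.4))
  expect_equal(rf_power_fraction(p_scaled), 0.08, tolerance = 1e-6)
  # default (two-revolution) duration: independent quadrature oracle
  p_def <- make_raff2_pulse(raff2_config(625, n_samples = 8192))
  oracle <- stats::integrate(function(t) sin(2 * pi * 625 * t)^2, 0,
                             sqrt(2) / 625,
                             rel.tol = 1e-12)$value / (sqrt(2) / 625)
  expect_equal(rf_power_fraction(p_def), oracle, tolerance = 1e-6)
  # zero-amplitude waveform
  expect_equal(rf_power_fraction(cw_pulse(0, 1e-3)), 0)
})

test_that("waveform CSV export round-trips the sampled columns", {
  wf <- make_raff2_pulse(raff2_config(625, n_samples = 64))
  f <- withr::local_tempfile(fileext = ".csv")
  export_waveform_csv(wf, f)
  d <- read.csv(f)
  expect_equal(d$omega1_hz, wf$omega1 / (2 * pi), tolerance = 1e-12)
  expect_equal(d$phase_rad, wf$phase, tolerance = 1e-12)
})
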