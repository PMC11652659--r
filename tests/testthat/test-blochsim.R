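tis <- tissue_params(m0 = 1, t1_ms = 1000, t2_ms = 45, traff2_ms = 80)

test_that("rotations conserve the magnetization norm without relaxation", {
  set.seed(11)
  for (i in 1:5) {
    m <- stats::rnorm(3)
    cfg <- raff2_config(sample(c(400, 625, 900), 1),
                        phi0 = stats::runif(1, 0, pi), n_samples = 256)
    wf <- make_raff2_pulse(cfg)
    out <- propagate_pulse(m, wf, tis, delta_omega0_hz = runif(1, -150, 150),
                           relax = FALSE)
    expect_lt(abs(sqrt(sum(out^2)) - sqrt(sum(m^2))) / sqrt(sum(m^2)),
              1e-9)
  }
})

test_that("continuous-wave spin lock reduces to exp(-t/T2) decay", {
  cw <- cw_pulse(400, 0.05, 2048)
  out <- propagate_pulse(c(1, 0, 0), cw, tis)  # M0 along the B1 axis
  expect_lt(abs(out[1] - exp(-0.05 / 0.045)), 1e-6)
})

test_that("free precession reproduces closed-form T1 recovery", {
  off <- cw_pulse(0, 1.0, 256)
  out <- propagate_pulse(c(0, 0, 0), off, tis)
  expect_lt(abs(out[3] - (1 - exp(-1000 / 1000))), 1e-9)
  # at t = T1 the recovery reaches 1 - 1/e of equilibrium
  out2 <- propagate_pulse(c(0, 0, 0), cw_pulse(0, 1.0, 64), tis)
  expect_equal(out2[3], 0.6321, tolerance = 1e-4)
})

test_that("propagation refuses too-coarse waveform sampling", {
  wf <- make_raff2_pulse(raff2_config(625, n_samples = 16))
  expect_error(propagate_pulse(c(0, 0, 1), wf, tis), "n_samples")
})

test_that("spoiler destroys transverse magnetization and recovers Mz", {
  out <- apply_spoiler(c(0.3, 0.4, 0.5), 0, tis)
  expect_equal(out, c(0, 0, 0.5))
  out <- apply_spoiler(c(0.1, 0.1, 0.5), 0.7e-3, tis)
  expect_equal(out[3], 1 - 0.5 * exp(-0.0007), tolerance = 1e-12)
  out <- apply_spoiler(c(0, 0, 0.2), 100, tis)   # gap >> T1
  expect_equal(out[3], 1, tolerance = 1e-12)
  expect_error(apply_spoiler(c(0, 0, 1), -1, tis), ">= 0")
})

test_that("saturation scales Mz by one minus efficiency", {
  expect_equal(apply_saturation(c(0.2, 0.1, 0.9), 1), c(0, 0, 0))
  expect_equal(apply_saturation(c(0, 0, 0.8), 0), c(0, 0, 0.8))
  expect_equal(apply_saturation(c(0, 0, 1), 0.95)[3], 0.05)
  expect_error(apply_saturation(c(0, 0, 1), 1.2), "\\[0, 1\\]")
})

test_that("forward-model series equals the three-parameter model", {
  ser <- simulate_series(tis, sequence_protocol(),
                         raff2_config(625, duration_s = 2.26e-3),
                         mode = "forward_model")
  s <- drop(ser$images)
  expect_equal(ser$prep_ms, printed_prep_ms, tolerance = 1e-12)
  expect_equal(s[1], 1.0)                    # S(0) = A + B
  expect_equal(s[5], 0.2)                    # S(sat) = B
  expect_equal(s[2:4], 0.8 * exp(-c(22.98, 46.66, 70.34) / 80) + 0.2)
})

test_that("phenomenological locking matches the forward model within 1%", {
  proto <- sequence_protocol()
  s1 <- drop(simulate_series(tis, proto, raff2_config(625),
                             mode = "phenomenological")$images)
  s2 <- drop(simulate_series(tis, proto, raff2_config(625),
                             mode = "forward_model",
                             a_frac = sin(70 * pi / 180),
                             b_frac = 0)$images)
  fin <- 1:4
  expect_lt(max(abs(s1[fin] - s2[fin]) / s2[fin]), 0.01)
})

test_that("phenomenological mode requires a ground-truth decay time", {
  bare <- tissue_params(1, 1000, 45)
  expect_error(simulate_series(bare, mode = "phenomenological"),
               "traff2")
})

test_that("protocol validation catches inconsistent settings", {
  expect_error(sequence_protocol(rest_period_s = -1), ">= 0")
  expect_error(sequence_protocol(saturation_efficiency = 2), "\\[0, 1\\]")
  expect_error(sequence_protocol(n_pulses = c(0, 8)), ">= 1")
})

test_that("sweep grids must contain their reference points", {
  expect_error(b0_b1_sweep(tis, delta_omega0_hz = c(-50, 50)),
               "reference 0")
  expect_error(b0_b1_sweep(tis, eta1 = c(0.4, 0.8)), "reference 1")
})

test_that("bSSFP readout yields a bounded transverse signal", {
  ser <- simulate_series(tis, sequence_protocol(readout = "bssfp"),
                         raff2_config(625), mode = "bloch")
  s <- drop(ser$images)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(s[1:4]) < 0))  # heavier weighting decays the signal
})
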