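test_that("weighted_series validates its inputs", {
  expect_error(weighted_series(array(1, c(2, 2, 4)), c(0, 10, 20)),
               "mismatch")
  expect_error(weighted_series(array(1, c(2, 2, 3)), c(0, Inf, Inf)),
               "at most one")
  expect_error(weighted_series(array(1, c(2, 2, 2)), c(-1, 10)), ">= 0")
})

test_that("noiseless model data is recovered exactly across the parameter space", {
  for (truth in list(c(0.8, 0.2, 80), c(1.5, 0.0, 50), c(0.3, 0.6, 150),
                     c(1.0, 0.1, 300))) {
    ser <- forward_series(truth[1], truth[2], truth[3])
    fit <- fit_traff2(ser)
    expect_true(fit$flags$converged[1])
    expect_equal(unname(coef(fit)["TRAFF2"]), truth[3], tolerance = 1e-3)
    expect_equal(unname(coef(fit)["A"]), truth[1], tolerance = 1e-5)
    expect_equal(unname(coef(fit)["B"]), truth[2], tolerance = 1e-5)
  }
})

test_that("fit is invariant to intensity rescaling and contrast order", {
  ser <- forward_series(0.9, 0.15, 120)
  f1 <- fit_traff2(ser)
  # scaling all images by c scales A, B and leaves TRAFF2 unchanged
  f2 <- fit_traff2(weighted_series(ser$images * 37, ser$prep_ms))
  expect_equal(f2$traff2_map, f1$traff2_map, tolerance = 1e-6)
  expect_equal(f2$a_map, 37 * f1$a_map, tolerance = 1e-6)
  expect_equal(f2$b_map, 37 * f1$b_map, tolerance = 1e-6)
  # permuting contrasts (with prep permuted identically) changes nothing
  p <- c(3, 1, 5, 2, 4)
  f3 <- fit_traff2(weighted_series(ser$images[, , p, drop = FALSE],
                                   ser$prep_ms[p]))
  expect_equal(f3$traff2_map, f1$traff2_map, tolerance = 1e-9)
})

test_that("degenerate voxels are flagged, not silently filled", {
  const <- weighted_series(rep(0.7, 5), printed_prep_ms)
  f <- fit_traff2(const)
  expect_true(f$flags$insufficient_signal[1] || f$flags$at_bound[1])
  expect_false(f$flags$converged[1])
  zero <- weighted_series(rep(0, 5), printed_prep_ms)
  fz <- fit_traff2(zero)
  expect_true(fz$flags$insufficient_signal[1])
  expect_error(fit_traff2(weighted_series(c(1, 0.5), c(0, 50))),
               "at least 3")
})

test_that("SD map is zero for noiseless data and matches the accessor", {
  ser <- forward_series()
  f <- fit_traff2(ser)
  expect_lt(f$sd_map[1], 1e-4)
  expect_equal(sd_map_from_residuals(f), f$sd_map, tolerance = 1e-9)
})

test_that("doubling the noise level doubles the median SD estimate", {
  sig0 <- drop(forward_series(0.8, 0.2, 80)$images)
  s_lo <- noisy_voxel_grid(sig0, printed_prep_ms, 400, 0.005, seed = 21)
  s_hi <- noisy_voxel_grid(sig0, printed_prep_ms, 400, 0.010, seed = 22)
  md_lo <- median(fit_traff2(s_lo)$sd_map, na.rm = TRUE)
  md_hi <- median(fit_traff2(s_hi)$sd_map, na.rm = TRUE)
  expect_equal(md_hi / md_lo, 2, tolerance = 0.1)
})

test_that("mono-exponential plumbing recovers closed-form decays", {
  # 2-parameter: T2-prep style series
  ser2 <- weighted_series(exp(-c(0, 25, 50) / 50), c(0, 25, 50))
  f2 <- fit_monoexp_decay(ser2, 2)
  expect_equal(f2$t_map[1], 50, tolerance = 1e-6)
  # 3-parameter with offset at 4 durations
  tp <- c(0, 20, 40, 80)
  ser3 <- weighted_series(0.7 * exp(-tp / 60) + 0.1, tp)
  f3 <- fit_monoexp_decay(ser3, 3)
  expect_equal(f3$t_map[1], 60, tolerance = 1e-4)
  expect_equal(f3$b_map[1], 0.1, tolerance = 1e-5)
  expect_error(fit_monoexp_decay(ser2, 4), "2 or 3")
})

test_that("log-linear initializer equals the closed-form slope", {
  tp <- c(0, 25, 50)
  ini <- loglin_decay_init(exp(-tp / 50), tp)
  expect_equal(unname(ini["t0"]), 50, tolerance = 1e-9)
  expect_equal(unname(ini["a0"]), 1, tolerance = 1e-9)
})

test_that("fit methods expose predictions and residuals consistently", {
  ser <- forward_series(0.8, 0.2, 80)
  f <- fit_traff2(ser)
  pred <- predict(f)
  expect_equal(drop(pred), drop(ser$images), tolerance = 1e-6)
  expect_equal(drop(residuals(f)), drop(ser$images) - drop(pred),
               tolerance = 1e-6)
  s <- summary(f)
  expect_s3_class(s, "summary.traff2_fit")
  expect_equal(s$n_converged, 1L)
  expect_output(print(f), "TRAFF2")
})
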