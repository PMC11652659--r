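test_that("coefficient of variation is exact and scale-invariant", {
  expect_equal(cv_percent(c(100, 100, 100)), 0)
  expect_equal(cv_percent(c(95, 100, 105)), 5)   # sample SD 5, mean 100
  set.seed(3)
  x <- stats::runif(20, 50, 150)
  expect_equal(cv_percent(x), cv_percent(x * 7.3), tolerance = 1e-12)
  expect_gte(cv_percent(x), 0)
  expect_error(cv_percent(100), "at least two")
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("segment table enforces the AHA slice/segment convention", {
  expect_error(segment_table("S1", 1, "mid", 2, 80), "inconsistent")
  expect_error(segment_table("S1", 1, "oblique", 7, 80), "basal, mid")
  tab <- segment_table("S1", 1, "apical", 14, 80, 5)
  expect_s3_class(tab, "segment_table")
})

test_that("variability statistics vanish for identical measurements", {
  tab <- simulate_segment_cohort(n_subjects = 3, n_reps = 2,
                                 between_cv = 0, within_cv = 0, seed = 1)
  st <- precision_reproducibility_intersubject(tab)
  expect_equal(st$wcv_bar, 0, tolerance = 1e-9)
  expect_equal(st$cv_bar, 0, tolerance = 1e-9)
})

test_that("variability statistics refuse degenerate designs", {
  tab <- simulate_segment_cohort(n_subjects = 1, n_reps = 3, seed = 1)
  expect_error(precision_reproducibility_intersubject(tab),
               "single subject")
  tab2 <- simulate_segment_cohort(n_subjects = 3, n_reps = 3, seed = 1)
  drop_cell <- !(tab2$subject == "S02" & tab2$repetition == 2 &
                   tab2$segment == 5)
  expect_error(precision_reproducibility_intersubject(tab2[drop_cell, ]),
               "S02")
})

test_that("hierarchical generative CVs are recovered from a cohort", {
  st <- precision_reproducibility_intersubject(
    simulate_segment_cohort(n_subjects = 7, n_reps = 3, between_cv = 10,
                            within_cv = 1, seed = 42))
  expect_equal(st$cv_bar, 10, tolerance = 3 / 10)
  expect_equal(st$wcv_bar, 1, tolerance = 0.5 / 1)
  expect_equal(st$wcv, 7.6, tolerance = 1e-6)  # SD-map driven precision
})

test_that("correlation and Bland-Altman handle exact agreement and shift", {
  x <- c(101.7, 150, 220, 310, 420, 550.8)
  ba <- pearson_and_bland_altman(x, x)
  expect_equal(ba$r2, 1)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  # a pure shift: unit slope, full correlation, bias equal to the shift
  ba2 <- pearson_and_bland_altman(x, x - 156.4)
  expect_equal(ba2$r2, 1)
  expect_equal(ba2$bias, -156.4)
  expect_equal(ba2$slope, 1, tolerance = 1e-9)
  # independent draws decorrelate
  set.seed(8)
  ba3 <- pearson_and_bland_altman(stats::rnorm(100), stats::rnorm(100))
  expect_lt(ba3$r2, 0.1)
  expect_error(pearson_and_bland_altman(rep(1, 5), stats::rnorm(5)),
               "zero variance")
})

test_that("2SD threshold separates voxels around remote mean + 2 SD", {
  img <- matrix(c(45, 50, 55, 59, 61, 50), 2, 3)
  remote <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE), 2, 3)
  # remote values 45, 50, 55, 50: mean 50, sd ~4.08 -> threshold ~58.2
  m <- scar_mask_2sd(img, remote)
  thr <- attr(m, "threshold")
  expect_true(m[img == 61])
  expect_false(m[2, 1])
  expect_equal(thr, 50 + 2 * stats::sd(c(45, 50, 55, 50)))
  # uniform image: empty mask and degenerate-threshold warning
  expect_warning(m2 <- scar_mask_2sd(matrix(5, 3, 3),
                                     matrix(TRUE, 3, 3)), "degenerate")
  expect_false(any(m2))
  expect_error(scar_mask_2sd(img, matrix(FALSE, 2, 3)), "empty")
})

test_that("AHA labelling partitions each slice with the standard counts", {
  ph <- make_sax_phantom(96)
  for (sl in c("basal", "mid", "apical")) {
    lab <- aha16_label(ph, slice_level = sl)
    expected <- switch(sl, basal = 1:6, mid = 7:12, apical = 13:16)
    expect_equal(sort(unique(lab[lab > 0])), expected)
    # exact partition: union is the mask, labels are disjoint by construction
    expect_identical(lab > 0, ph$myocardium_mask)
  }
  expect_error(aha16_label(ph$myocardium_mask, c(48, 48), c(48, 48)),
               "coincides")
})

test_that("rotating the RV insertion by 60 degrees permutes mid labels cyclically", {
  ph <- make_sax_phantom(96)
  lab0 <- aha16_label(ph, slice_level = "mid")
  ctr <- ph$lv_center
  v <- ph$rv_insertion - ctr
  rot <- pi / 3  # 60 degrees counterclockwise in (x = col, y = -row)
  x <- v[2]; y <- -v[1]
  rv2 <- c(ctr[1] - (x * sin(rot) + y * cos(rot)),
           ctr[2] + (x * cos(rot) - y * sin(rot)))
  lab1 <- aha16_label(ph$myocardium_mask, ctr, rv2, "mid")
  sel <- ph$myocardium_mask
  # brute-force: rotating the origin forward shifts every voxel's angular
  # offset back by one 60-degree bin
  shifted <- (lab0[sel] - 7 - 1) %% 6 + 7
  expect_gt(mean(lab1[sel] == shifted), 0.99)  # boundary voxels may differ
})

test_that("bullseye summary conserves means", {
  tab <- segment_table(rep("S1", 16), rep(1, 16),
                       c(rep("basal", 6), rep("mid", 6), rep("apical", 4)),
                       1:16, rep(79.1, 16), rep(5, 16))
  be <- bullseye_summary(tab)
  expect_equal(be$global$mean_ms, 79.1, tolerance = 1e-12)
  expect_equal(nrow(be$per_segment), 16)
  # grand mean reproduced from an arbitrary table
  tab2 <- simulate_segment_cohort(seed = 2)
  be2 <- bullseye_summary(tab2)
  expect_equal(be2$global$mean_ms, mean(be2$per_segment$mean_ms),
               tolerance = 1e-12)
  # slice means are unweighted averages of their segment means
  bas <- be2$per_segment[be2$per_segment$slice == "basal", "mean_ms"]
  expect_equal(be2$per_slice$mean_ms[be2$per_slice$slice == "basal"],
               mean(bas), tolerance = 1e-12)
})

test_that("segment statistics aggregate a uniform map to its value", {
  ph <- make_sax_phantom(96)
  tmap <- matrix(79.1, 96, 96)
  tab <- segment_map_stats(tmap, NULL, ph$myocardium_mask, ph$lv_center,
                           ph$rv_insertion, "mid")
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$mean_ms == 79.1))
})
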