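test_that("spherical target extraction matches brute-force enumeration", {
  vox <- c(1.875, 1.875, 5)
  # uniform map: median is the value, count is the sphere voxel count
  u <- array(3.7, c(16, 16, 6))
  ctr <- c(14, 14, 12)
  et <- extract_target(u, ctr, vox, radius_mm = 5)
  expect_equal(et$value, 3.7)
  expect_equal(et$n_voxels, length(oracle_sphere_values(u, ctr, vox, 5)))
  # radius below half a voxel at a voxel centre: that voxel only
  one <- extract_target(u, c(5 * 1.875, 5 * 1.875, 10), vox, radius_mm = 0.5)
  expect_equal(one$n_voxels, 1)
  # two-valued phantom split by a plane through the centre
  m <- array(1, c(16, 16, 6)); m[9:16, , ] <- 2
  ctr2 <- c(7.5 * 1.875, 10, 10)
  et2 <- extract_target(m, ctr2, vox, radius_mm = 5)
  expect_equal(et2$value, median(oracle_sphere_values(m, ctr2, vox, 5)))
  expect_equal(et2$n_voxels, length(oracle_sphere_values(m, ctr2, vox, 5)))
  expect_error(extract_target(u, c(1000, 0, 0), vox), "field of view")
  na_map <- array(NA_real_, c(16, 16, 6))
  expect_error(extract_target(na_map, ctr, vox), "no valid voxels")
})

test_that("Bland-Altman limits are exactly mean +/- 1.96 sample SD", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_difference, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  ba1 <- bland_altman(c(4, 4, 4), c(5, 5, 5))   # d = {-1,-1,-1}
  expect_equal(ba1$mean_difference, -1)
  expect_equal(c(ba1$loa_low, ba1$loa_high), c(-1, -1))
  ba2 <- bland_altman(c(0, -1, -2), c(0, 0, 0)) # d = {0,-1,-2}
  expect_equal(ba2$mean_difference, -1)
  expect_equal(ba2$sd_difference, 1)
  expect_equal(ba2$loa_low, -2.96)
  expect_equal(ba2$loa_high, 0.96)
  # identity holds on random data
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40)
  ba <- bland_altman(x, y)
  expect_equal(ba$loa_low, ba$mean_difference - 1.96 * sd(x - y))
  expect_equal(ba$loa_high, ba$mean_difference + 1.96 * sd(x - y))
  expect_lte(ba$loa_low, ba$mean_difference)
  expect_gte(ba$loa_high, ba$mean_difference)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("Pearson correlation and its t-based p-value are correct", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  # exact-r construction at n = 26, r = 0.49: p from the t oracle
  set.seed(8)
  z1 <- as.numeric(scale(rnorm(26)))
  z2 <- as.numeric(scale(residuals(lm(rnorm(26) ~ z1))))
  y <- 0.49 * z1 + sqrt(1 - 0.49^2) * z2
  ct <- correlate(z1, y)
  expect_equal(ct$r, 0.49, tolerance = 1e-10)
  t_or <- 0.49 * sqrt(24 / (1 - 0.49^2))
  expect_equal(ct$p, 2 * pt(-abs(t_or), df = 24), tolerance = 1e-10)
  expect_lt(abs(ct$p - 0.011), 1e-3)
  # affine invariance (positive slope)
  set.seed(9)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(correlate(3 * a + 2, 0.5 * b - 1)$r, correlate(a, b)$r,
               tolerance = 1e-12)
  expect_error(correlate(a, rep(1, 30)), "zero variance")
  expect_error(correlate(1:2, 1:2), "3 pairs")
})

test_that("Mann-Whitney U matches brute-force pairwise counting", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(3); y <- rnorm(3)
    gc <- group_compare(c(x, y), rep(c("a", "b"), each = 3))
    expect_equal(gc$u, oracle_u_statistic(x, y))
  }
  # complete separation: U = n1*n2, minimal exact p = 2/choose(6,3)
  gc <- group_compare(c(10, 11, 12, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(gc$u, 9)
  expect_equal(gc$p, 2 / choose(6, 3), tolerance = 1e-12)
  expect_error(group_compare(1:4, rep("a", 4)), "two groups")
  # Shapiro-Wilk reported per group
  set.seed(13)
  gc2 <- group_compare(rnorm(20), rep(c("a", "b"), each = 10))
  expect_equal(nrow(gc2$shapiro), 2)
  expect_true(all(gc2$shapiro$p > 0 & gc2$shapiro$p <= 1))
})

test_that("VSI difference t-test flags zero-variance pairs", {
  zt <- vsi_difference_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(zt$zero_variance)
  tt <- vsi_difference_test(c(5, 6, 7, 8), c(4, 4, 6, 6))
  expect_equal(tt$p, t.test(c(5, 6, 7, 8), c(4, 4, 6, 6), paired = TRUE)$p.value)
})

test_that("agreement report reproduces independently computed statistics", {
  co <- make_paired_cohort(n_targets = 26, seed = 7)
  rep_ <- build_report(co)
  expect_s3_class(rep_, "agreement_report")
  # recomputation oracle on the same table
  expect_equal(rep_$correlations$r[rep_$correlations$pair == "rcbv_vs_density"],
               cor(co$rcbv, co$density))
  expect_equal(rep_$correlations$p[rep_$correlations$pair == "vsi_mri_vs_caliber"],
               cor.test(co$vsi_mri, co$vsi_histo)$p.value)
  d <- co$vsi_mri - co$vsi_histo
  expect_equal(rep_$bland_altman$mean_difference, mean(d))
  expect_equal(rep_$bland_altman$loa_high, mean(d) + 1.96 * sd(d))
  gt <- rep_$group_tests
  wt <- wilcox.test(co$rcbv[co$grade == "III"], co$rcbv[co$grade == "IV"])
  expect_equal(gt$p[gt$variable == "rcbv"], wt$p.value)
  expect_equal(rep_$t_test$p, t.test(co$vsi_mri, co$vsi_histo, paired = TRUE)$p.value)
  # tidy/glance interfaces
  expect_equal(nrow(tidy(rep_)), 4)
  expect_equal(glance(rep_)$n_targets, 26)
})

test_that("perfect caliber correlation propagates to the report", {
  co <- make_paired_cohort(n_targets = 12, rho_caliber = 1, seed = 2)
  rep_ <- build_report(co)
  expect_equal(rep_$correlations$r[rep_$correlations$pair == "vsi_mri_vs_caliber"],
               1, tolerance = 1e-9)
  expect_error(build_report(co[1:2, ]), "3 complete")
  co_na <- co; co_na$density[2] <- NA
  expect_message(rep_na <- build_report(co_na), "excluding")
  expect_equal(rep_na$n_targets, 11)
})

test_that("report plots build without error", {
  co <- make_paired_cohort(n_targets = 20, seed = 3)
  rep_ <- build_report(co)
  expect_s3_class(ggplot2::autoplot(rep_$bland_altman), "ggplot")
  expect_s3_class(ggplot2::autoplot(rep_), "ggplot")
  expect_s3_class(plot_correlations(rep_), "ggplot")
})
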