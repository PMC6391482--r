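test_that("design matrix reproduces the printed coefficient rows", {
  y <- sage_design_matrix(c(14.0, 34.1, 58.0, 92.4))
  expect_equal(y[1, ], c(1, 0, -14.0, 0))
  expect_equal(y[2, ], c(1, 0, -34.1, 0))
  expect_equal(y[3, ], c(1, -1, -34.4, -23.6))
  expect_equal(y[4, ], c(1, -1, 0, -92.4))
})

test_that("design matrix is invertible for valid echo-time sets", {
  set.seed(1)
  for (i in 1:25) {
    te12 <- sort(runif(2, 5, 45))
    te4 <- runif(1, 70, 120)
    te3 <- runif(1, te4 / 2 + 1, te4 - 5)
    tes <- c(te12, te3, te4)
    if (any(diff(tes) <= 0)) next
    y <- sage_design_matrix(tes)
    expect_gt(abs(det(y)), 0)
  }
  y <- sage_design_matrix(c(1, 2, 3, 4))
  expect_equal(solve(y) %*% y, diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(echo_times(c(14, 34, 40, 92)), "te3")
  expect_error(echo_times(c(14, 34, 58)), "4 echo")
})

test_that("voxel fit exactly inverts the forward model", {
  tes <- c(14.0, 34.1, 58.0, 92.4)
  s <- oracle_sage_signals(1000, 1.05, 0.020, 0.010, tes)
  f <- fit_sage_voxel(s, tes)
  expect_equal(f$s0, 1000, tolerance = 1e-9)
  expect_equal(f$delta, 1.05, tolerance = 1e-9)
  expect_equal(f$r2star, 0.020, tolerance = 1e-9)
  expect_equal(f$r2, 0.010, tolerance = 1e-9)
  expect_false(f$delta_flagged)
  # delta = 1 phantom: fitted ln(delta) = 0
  f1 <- fit_sage_voxel(oracle_sage_signals(800, 1, 0.03, 0.015, tes), tes)
  expect_equal(log(f1$delta), 0, tolerance = 1e-12)
  # flat decay: equal signals, delta 1 -> zero rates, s0 = signal
  ff <- fit_sage_voxel(rep(250, 4), tes)
  expect_equal(ff$r2star, 0, tolerance = 1e-12)
  expect_equal(ff$r2, 0, tolerance = 1e-12)
  expect_equal(ff$s0, 250, tolerance = 1e-9)
  # non-positive signal: masked, not an error
  bad <- fit_sage_voxel(c(100, -1, 50, 25), tes)
  expect_true(is.na(bad$s0))
})

test_that("scaling all four signals rescales only S0 (log-linearity)", {
  tes <- c(14.0, 34.1, 58.0, 92.4)
  set.seed(42)
  for (i in 1:20) {
    s0 <- runif(1, 100, 2000); delta <- runif(1, 0.9, 1.3)
    r2s <- runif(1, 0.005, 0.05); r2 <- runif(1, 0.003, r2s)
    sig <- oracle_sage_signals(s0, delta, r2s, r2, tes)
    c_ <- runif(1, 0.1, 10)
    f1 <- fit_sage_voxel(sig, tes)
    f2 <- fit_sage_voxel(c_ * sig, tes)
    expect_equal(f2$s0 / f1$s0, c_, tolerance = 1e-9)
    expect_equal(f2$delta, f1$delta, tolerance = 1e-9)
    expect_equal(f2$r2star, f1$r2star, tolerance = 1e-9)
    expect_equal(f2$r2, f1$r2, tolerance = 1e-9)
  }
})

test_that("series fit recovers the ground-truth rate time courses", {
  tc <- tiny_sage_sim(noise_sigma = 0)
  fit <- fit_sage_series(tc$sim$signal, tc$sim$echo_times)
  expect_equal(fit$invalid_fraction, 0)
  lab <- tc$sim$truth$labels
  k <- match("tumor", tc$phantom$classes$class)
  vox <- which(lab == k, arr.ind = TRUE)[1, ]
  truth_r2s <- tc$phantom$classes$r2star0[k] + tc$sim$truth$dr2star_obs[k, ]
  expect_equal(fit$r2star[, vox[1], vox[2], vox[3]], truth_r2s,
               tolerance = 1e-9)
  # noiseless fitted delta is time-constant
  expect_lt(max(fit$delta_variation[lab == k], na.rm = TRUE), 1e-7)
  # all-false mask: empty result, no error
  empty <- fit_sage_series(tc$sim$signal, tc$sim$echo_times,
                           mask = array(FALSE, dim(lab)))
  expect_true(all(is.na(empty$r2star)))
  expect_error(fit_sage_series(tc$sim$signal[1:3, , , , ], tc$sim$echo_times),
               "4 echoes")
})

test_that("delta curves are baseline-zero with peaks near the class truth", {
  tc <- tiny_sage_sim(noise_sigma = 0)
  fit <- fit_sage_series(tc$sim$signal, tc$sim$echo_times)
  rg <- delta_curves(fit)
  lab <- tc$sim$truth$labels
  k <- match("tumor", tc$phantom$classes$class)
  vox <- which(lab == k, arr.ind = TRUE)[1, ]
  # baseline-mean-zero by construction
  bw <- rg$baseline_window
  expect_equal(mean(rg$d_r2star_t[bw, vox[1], vox[2], vox[3]]), 0,
               tolerance = 1e-12)
  # peak near the class peak within bolus sampling/smoothing discretization
  expect_equal(rg$d_r2star_max[vox[1], vox[2], vox[3]],
               tc$phantom$classes$peak_dr2star[k], tolerance = 0.07)
  expect_equal(rg$d_r2_max[vox[1], vox[2], vox[3]],
               tc$phantom$classes$peak_dr2[k], tolerance = 0.07)
})

test_that("constant series gives identically zero delta curves", {
  ph <- phantom_spec(grid_shape = c(6, 6, 2), noise_sigma = 0)
  sim <- simulate_sage_dataset(ph, bolus_model(amplitude = 0), n_timepoints = 10)
  fit <- fit_sage_series(sim$signal, sim$echo_times)
  rg <- delta_curves(fit)   # no bolus: whole series becomes the baseline
  expect_equal(length(rg$baseline_window), 10)
  expect_equal(max(abs(rg$d_r2star_t), na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(max(rg$d_r2star_max, na.rm = TRUE), 0, tolerance = 1e-10)
  # explicit all-timepoint baseline on a constant series also yields zero
  rg2 <- delta_curves(fit, baseline_window = 1:10)
  expect_equal(max(abs(rg2$d_r2star_t), na.rm = TRUE), 0, tolerance = 1e-10)
})

test_that("a baseline window that contains the bolus peak is refused", {
  tc <- tiny_sage_sim(noise_sigma = 0)
  fit <- fit_sage_series(tc$sim$signal, tc$sim$echo_times)
  peak_idx <- which.max(tc$sim$truth$bolus_curve)
  expect_error(
    suppressWarnings(delta_curves(fit, baseline_window = (peak_idx - 2):(peak_idx + 2))),
    "peak")
  expect_error(delta_curves(fit, baseline_window = 1:2), ">= 3")
})

test_that("peak dR2* error decreases monotonically with SNR", {
  tes <- echo_times()
  snrs <- c(50, 100, 200)
  nvox <- 1000
  ph <- phantom_spec(grid_shape = c(nvox, 1, 1),
                     labels = array(3L, c(nvox, 1, 1)), noise_sigma = 0)
  truth_peak <- ph$classes$peak_dr2star[3]
  med_err <- sapply(seq_along(snrs), function(i) {
    phs <- phantom_spec(grid_shape = c(nvox, 1, 1),
                        labels = array(3L, c(nvox, 1, 1)),
                        noise_sigma = ph$classes$s0[3] / snrs[i],
                        seed = 100 + i)
    sim <- simulate_sage_dataset(phs, bolus_model(t0 = 20), n_timepoints = 40)
    fit <- fit_sage_series(sim$signal, sim$echo_times)
    rg <- delta_curves(fit, baseline_window = 3:7)
    median(abs(rg$d_r2star_max - truth_peak), na.rm = TRUE)
  })
  expect_true(all(diff(med_err) < 0))
})
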