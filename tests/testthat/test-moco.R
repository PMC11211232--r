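test_that("gradient entropy matches its closed forms", {
  # linear ramp: uniform gradient magnitude over the ROI
  n <- 12
  ramp <- matrix(rep(seq_len(n), n), n)
  roi100 <- list(y = 2:11, z = 2:11)
  expect_equal(gradient_entropy(ramp, roi100), log(100), tolerance = 1e-12)
  # single-pixel ROI: a point distribution has zero entropy
  expect_equal(gradient_entropy(ramp, list(y = 5, z = 5)), 0)
  # two equal-gradient pixels: ln 2
  expect_equal(gradient_entropy(ramp, list(y = 5, z = 5:6)), log(2))
  # zero-gradient image: infinity sentinel
  expect_identical(gradient_entropy(matrix(1, 8, 8)), Inf)
  expect_error(gradient_entropy(ramp, list(y = integer(0), z = 1)), "ROI")
  expect_error(gradient_entropy(ramp, list(y = 1:20, z = 1)), "outside")
})

test_that("k-space correction is the exact inverse of the simulated shift", {
  ph_mov <- make_phantom(phantom_config(grid_size = 16, voxel_mm = 2,
                                        resp_amplitude_mm = c(0, 4, 6),
                                        vessel_radius_mm = 5))
  ph_still <- make_phantom(phantom_config(grid_size = 16, voxel_mm = 2,
                                          resp_amplitude_mm = c(0, 0, 0),
                                          vessel_radius_mm = 5))
  cfg <- sequence_config("FISS", mode = "2d", n_interleaves = 2, fov_mm = 32,
                         resolution_mm = 2, oversampling = 1)
  sched <- build_schedule(cfg, 0)
  coils <- make_coil_maps(2, 16, 2, seed = 3)
  raw_mov <- simulate_scan(ph_mov, sched, coils, noise_sd = 0)
  raw_still <- simulate_scan(ph_still, sched, coils, noise_sd = 0)
  model <- motion_model(c(0, 4, 6), ph_mov$resp_curve_fn(sched$t), sched$t)
  corr <- apply_respiratory_correction(raw_mov, model)
  expect_lt(max(Mod(corr$samples - raw_still$samples)), 1e-10)
  # zero model leaves the data bitwise unchanged
  zero <- motion_model(c(0, 0, 0), ph_mov$resp_curve_fn(sched$t), sched$t)
  expect_identical(apply_respiratory_correction(raw_mov, zero)$samples,
                   raw_mov$samples)
  # applying c then -c is the identity
  neg <- motion_model(-model$coeffs_mm, model$resp_values, model$times)
  back <- apply_respiratory_correction(corr, neg)
  expect_lt(max(Mod(back$samples - raw_mov$samples)), 1e-12)
})

test_that("fNAV fitting contract: degenerate input, bounds, monotone trace", {
  fx <- tiny_raw()
  expect_warning(m0 <- fit_fnav_coefficients(fx$raw, rep(0, nrow(fx$raw$schedule))),
                 "degenerate")
  expect_equal(m0$coeffs_mm, c(0, 0, 0))
  expect_error(motion_model(c(0, 0, 30), 0, 0), "bound")
})

test_that("fNAV recovers an in-plane displacement on a small phantom", {
  ph <- make_phantom(phantom_config(grid_size = 32, voxel_mm = 2,
                                    resp_amplitude_mm = c(0, 0, 6),
                                    vessel_radius_mm = 6))
  cfg <- sequence_config("FISS", mode = "2d", n_interleaves = 24, fov_mm = 64,
                         resolution_mm = 2, oversampling = 1)
  sched <- build_schedule(cfg, 0)
  coils <- make_coil_maps(2, 32, 2, seed = 3)
  raw <- simulate_scan(ph, sched, coils, noise_sd = 0)
  r <- ph$resp_curve_fn(sched$t)
  fit <- fit_fnav_coefficients(raw, r, bound_mm = 12, stride = 2)
  expect_lt(max(abs(fit$coeffs_mm - c(0, 0, 6))), 1.5)
  # accepted objective trace decreases monotonically
  expect_true(all(diff(fit$trace) <= 1e-12))
  # the minimizer is at least as sharp as the uncorrected image
  ctx <- synaps4d:::fnav_context(raw, r, NULL, 2L)
  expect_lte(fit$entropy, synaps4d:::fnav_objective(ctx, c(0, 0, 0)))
})
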