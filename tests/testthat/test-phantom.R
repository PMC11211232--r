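test_that("phantom construction honours its contract", {
  ph <- make_phantom(phantom_config())
  expect_length(ph$geometry$vessels, 2)
  expect_gt(ph$vmax_peak_cm_s, 0)
  # determinism: identical config yields bitwise-identical rendered frames
  ph2 <- make_phantom(phantom_config())
  expect_identical(render_frame(ph, 0.123, "FISS"),
                   render_frame(ph2, 0.123, "FISS"))
  # invalid geometry rejected
  expect_error(phantom_config(grid_size = 16, vessel_radius_mm = 10),
               "FOV/4")
  expect_error(phantom_config(resp_amplitude_mm = c(0, 0, 30)), "25 mm")
})

test_that("zero respiratory amplitude means zero displacement at all times", {
  ph <- make_phantom(phantom_config(resp_amplitude_mm = c(0, 0, 0)))
  d <- synaps4d:::resp_displacement(ph, seq(0, 10, by = 0.37))
  expect_true(all(d == 0))
})

test_that("rendered contrasts follow the tissue table", {
  ph <- make_phantom(phantom_config())
  fr <- render_frame(ph, 0.5, "FISS", apply_resp = FALSE)
  # blood pool centre vs myocardial shell: ratio 1.5 by construction
  ctr <- ph$geometry$heart$center
  ax <- synaps4d:::axis_coords_mm(64, 2)
  bp <- c(which.min(abs(ax - ctr[1])), which.min(abs(ax - ctr[2])))
  myo <- c(bp[1], which.min(abs(ax - (ctr[2] + 15))))
  expect_equal(fr[bp[1], bp[2]] / fr[myo[1], myo[2]], 1.5, tolerance = 1e-6)
  # fat ring is suppressed under FISS, bright under PC
  fat_px <- c(33, which.min(abs(ax - 52)))
  expect_equal(fr[fat_px[1], fat_px[2]], 0)
  pc <- render_frame(ph, 0.5, "PC", apply_resp = FALSE)
  expect_gt(pc[fat_px[1], fat_px[2]], 1)
  # FISS blood/myocardium ratio strictly exceeds the PC ratio
  expect_gt(fr[bp[1], bp[2]] / fr[myo[1], myo[2]],
            pc[bp[1], bp[2]] / pc[myo[1], myo[2]])
})

test_that("frames are periodic in the cardiac cycle", {
  ph <- make_phantom(phantom_config())
  rr <- 1 / ph$config$heart_rate_hz
  expect_equal(render_frame(ph, 0.2, "FISS", apply_resp = FALSE),
               render_frame(ph, 0.2 + rr, "FISS", apply_resp = FALSE),
               tolerance = 1e-12)
})

test_that("respiratory displacement equals c * r(t) in the rendered frames", {
  # 8 mm amplitude with r = -1 displaces by exactly 4 voxels of 2 mm
  ph <- make_phantom(phantom_config(resp_amplitude_mm = c(0, 8, 0)))
  t0 <- 0  # r(0) = -1 at the breathing trough
  expect_equal(ph$resp_curve_fn(t0), -1)
  shifted <- render_frame(ph, t0, "FISS", apply_resp = TRUE)
  ref <- render_frame(ph, t0, "FISS", apply_resp = FALSE)
  # scene moved by -8 mm along y: frame content shifts down 4 rows
  expect_equal(shifted[1:60, ], ref[5:64, ], tolerance = 1e-12)
})

test_that("vessel velocity is parabolic and integrates to the stroke volume", {
  ph <- make_phantom(phantom_config())
  t_sys <- 0.35 / 2 / ph$config$heart_rate_hz  # mid-systole, peak flow
  phase <- ph$cardiac_phase_fn(t_sys)
  v <- render_velocity(ph, t_sys, apply_resp = FALSE)
  ctr <- synaps4d:::vessel_center_pixel(ph, "AAo")
  vmax <- synaps4d:::vmax_at(ph, phase)
  # on-axis voxel carries (almost) the peak velocity: 2 mm partial-volume
  # averaging of the parabola lowers it by <rho^2>/R^2 ~ 0.7%
  expect_equal(v[ctr[1], ctr[2], 1], vmax, tolerance = 0.01)
  # at the wall the profile reaches zero
  rv <- synaps4d:::vessel_radius_at(ph, phase)
  wall <- ctr + c(round(rv / 2), 0)
  expect_lt(abs(v[wall[1] + 3, wall[2], 1]), vmax * 0.1)
  # cross-section mean velocity is vmax / 2 (parabolic profile)
  g <- ph$geometry$vessels$AAo
  ax <- synaps4d:::axis_coords_mm(64, 2)
  rho2 <- outer((ax - g$center[1])^2, (ax - g$center[2])^2, "+")
  inside <- rho2 <= (0.8 * rv)^2  # interior, away from partial-volume rim
  mean_interior <- vmax * mean(1 - rho2[inside] / rv^2)
  expect_equal(mean(v[, , 1][inside]), mean_interior, tolerance = 0.02)
  # per-beat flow integral equals the stroke volume within 2%
  # (numeric quadrature over a fine time grid, summing v * pixel area)
  tt <- seq(0, 1 / ph$config$heart_rate_hz, length.out = 121)[-1]
  q <- vapply(tt, function(t) {
    vt <- render_velocity(ph, t, apply_resp = FALSE)
    sum(vt[, , 1][vt[, , 1] > 0]) * ph$config$voxel_mm^2 * 0.01
  }, numeric(1))
  vol <- mean(q) / ph$config$heart_rate_hz
  expect_equal(vol, ph$config$stroke_volume_ml, tolerance = 0.02)
})

test_that("pilot-tone simulation is a seeded low-rank mixture", {
  ph <- make_phantom(phantom_config())
  clean <- simulate_pt(ph, 30, noise_sd = 0, drift_per_min = 0)
  expect_equal(nrow(clean$data), 12)  # 12-channel body-coil context
  expect_lte(qr(clean$data)$rank, 2)
  # determinism
  again <- simulate_pt(ph, 30, noise_sd = 0.1)
  expect_identical(again$data, simulate_pt(ph, 30, noise_sd = 0.1)$data)
  # sampling-rate guard
  expect_error(simulate_pt(ph, 30, fs = 2), "too low")
})
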