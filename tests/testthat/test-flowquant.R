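test_that("plane extraction projects velocity on the plane normal", {
  vel <- array(0, c(4, 4, 2, 3))
  vel[, , , 3] <- 100
  vol <- flow4d(vel, array(1, c(4, 4, 2)), 150, 2)
  ext <- extract_plane(vol, plane_spec(c(0, 0, 1)))
  expect_true(all(ext$v_through == 100))
  vel2 <- array(0, c(4, 4, 2, 3)); vel2[, , , 1] <- 50
  vol2 <- flow4d(vel2, array(1, c(4, 4, 2)), 150, 2)
  expect_true(all(extract_plane(vol2, plane_spec(c(0, 0, 1)))$v_through == 0))
  expect_error(plane_spec(c(1, 1, 0)), "unit")
})

test_that("dynamic segmentation recovers the vessel area and overlap", {
  ph <- make_phantom(phantom_config())
  P <- 6
  phases <- (seq_len(P) - 0.5) / P
  rr <- 1 / ph$config$heart_rate_hz
  mag <- array(0, c(64, 64, P))
  for (p in seq_len(P)) mag[, , p] <- render_frame(ph, phases[p] * rr, "FISS",
                                                   apply_resp = FALSE)
  seed <- synaps4d:::vessel_center_pixel(ph, "AAo")
  masks <- segment_vessel_dynamic(mag, seed)
  for (p in seq_len(P)) {
    truth <- true_vessel_mask(ph, phases[p], "AAo")
    area_true <- pi * synaps4d:::vessel_radius_at(ph, phases[p])^2
    expect_lt(abs(sum(masks[, , p]) * 4 - area_true) / area_true, 0.1)
    expect_gte(dice_coefficient(masks[, , p], truth), 0.9)
  }
  # on low-contrast PC magnitude with noise the tracing cannot follow the
  # true dynamic lumen: its area error is far larger than on bright-blood
  # FISS contrast (paired noise realizations), mirroring the static or
  # flooded native-contrast areas seen in practice
  set.seed(31)
  noise <- array(rnorm(64 * 64 * P, 0, 0.08), c(64, 64, P))
  mag_pc <- array(0, c(64, 64, P))
  for (p in seq_len(P)) mag_pc[, , p] <- render_frame(ph, phases[p] * rr, "PC",
                                                      apply_resp = FALSE)
  area_true <- pi * synaps4d:::vessel_radius_at(ph, phases)^2
  area_err <- function(m) {
    masks <- tryCatch(segment_vessel_dynamic(m, seed), error = function(e) NULL)
    if (is.null(masks)) return(Inf)  # lost the vessel entirely
    mean(abs(colSums(matrix(masks, 64 * 64, P)) * 4 - area_true))
  }
  expect_gt(area_err(mag_pc + noise), area_err(mag + noise))
})

test_that("flow metrics integrate the velocity over the mask", {
  # constant 100 mL/s across 1 s: net volume 100 mL, peak flow 100 mL/s
  masks <- array(TRUE, c(5, 5, 4))
  vel <- array(100 / (25 * 4 * 0.01), c(5, 5, 4))  # uniform velocity
  m <- flow_metrics(masks, vel, pixel_mm = 2, rr_s = 1)
  expect_equal(m$net_volume_ml, 100)
  expect_equal(m$peak_flow_ml_s, 100)
  expect_true(all(m$area_mm2 == 100))
  # zero velocity: zero net volume
  expect_equal(flow_metrics(masks, vel * 0, 2, 1)$net_volume_ml, 0)
  # parabolic profile, vmax 100 cm/s, R 10 mm: Q = vmax/2 * pi R^2 = 157.1
  ax <- synaps4d:::axis_coords_mm(24, 2)
  rho2 <- outer(ax^2, ax^2, "+")
  vpar <- array(100 * pmax(1 - rho2 / 100, 0), c(24, 24, 1))
  mpar <- array(rho2 <= 100, c(24, 24, 1))
  q <- flow_metrics(mpar, vpar, 2, 1)$q_ml_s
  expect_equal(q, 157.08, tolerance = 0.05)
})

test_that("contrast ratio divides mean ROI intensities", {
  img <- matrix(2, 8, 8)
  img[1:3, 1:3] <- 3
  expect_equal(contrast_ratio(img, list(y = 1:3, z = 1:3),
                              list(y = 6:8, z = 6:8)), 1.5)
  expect_equal(contrast_ratio(img, list(y = 6:8, z = 1:3),
                              list(y = 6:8, z = 6:8)), 1)
  expect_error(contrast_ratio(img * 0, list(y = 1, z = 1),
                              list(y = 2, z = 2)), "zero")
})

test_that("Dice coefficient closed forms and symmetry", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(dice_coefficient(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  c2 <- matrix(FALSE, 4, 4); c2[1:2, 2:3] <- TRUE  # |A|=|B|=4, overlap 2
  expect_equal(dice_coefficient(a, c2), 0.5)
  expect_equal(dice_coefficient(c2, a), 0.5)
  empty <- matrix(FALSE, 4, 4)
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_error(dice_coefficient(a, matrix(FALSE, 3, 3)), "shapes")
})

test_that("agreement statistics match their closed forms", {
  a <- c(1, 2, 3, 4, 5)
  st <- agreement_stats(a, a)
  expect_equal(st$bias, 0)
  expect_equal(diff(st$loa), 0)
  expect_equal(st$pearson_r, 1)
  expect_equal(st$r_squared, 1)
  expect_equal(st$wilcoxon_p, 1)
  st2 <- agreement_stats(a + 5, a)
  expect_equal(st2$bias, 5)
  expect_equal(sd(a + 5 - a), 0)
  # printed toy pair: mean absolute error 10
  st3 <- agreement_stats(c(100, 110, 100), c(90, 120, 100))
  expect_equal(st3$mean_abs_error, 20 / 3)
  expect_equal(agreement_stats(c(100, 110, 100, 110),
                               c(90, 120, 90, 120))$mean_abs_error, 10)
  # zero-variance input flagged
  expect_true(agreement_stats(rep(1, 4), rep(2, 4))$zero_variance)
  expect_error(agreement_stats(1:2, 1:2), "length")
})

test_that("peak-systole alignment makes all argmax indices coincide", {
  base <- c(0, 1, 5, 2, 0, 0, 0, 0)
  shifted <- c(base[7:8], base[1:6])  # peak moved from 3 to 5
  al <- align_peak_systole(list(base, shifted))
  expect_equal(al$shifts, c(0L, 2L))
  expect_equal(which.max(al$aligned[[2]]), which.max(base))
  expect_equal(al$aligned[[2]], base)
  same <- align_peak_systole(list(base, base))
  expect_equal(same$shifts, c(0L, 0L))
})
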