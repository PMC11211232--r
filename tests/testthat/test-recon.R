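test_that("gridded reconstruction is a calibrated adjoint", {
  fx <- tiny_raw()
  raw <- fx$raw
  img <- gridded_recon(raw)
  expect_equal(dim(img), c(16, 16))
  # point object: impulse response peaks at the object location
  delta <- matrix(0, 16, 16); delta[9, 9] <- 1
  g <- synaps4d:::acq_geometry(raw)
  raw_pt <- raw
  for (c in 1:2) {
    y <- synaps4d:::radial_nudft_forward(
      cbind(as.vector(raw$coils[, , c]) * as.vector(delta)),
      g$coords, g$dirs, integer(nrow(raw$schedule)), g$rs$dk, g$rs$ns)
    raw_pt$samples[, , c] <- t(y)
  }
  psf <- Mod(gridded_recon(raw_pt))
  expect_equal(which(psf == max(psf)), 16 * 8 + 9)  # (9, 9) linear index
  # linearity: doubling the data doubles the image
  raw2 <- raw; raw2$samples <- raw2$samples * 2
  expect_equal(gridded_recon(raw2), img * 2, tolerance = 1e-12)
  # empty phase bins are reported by index
  bins <- rep(0L, nrow(raw$schedule))
  expect_error(gridded_recon(raw, bins, n_phases = 2L), "bin 1")
})

test_that("normalization scales the gridded maximum to one and is idempotent", {
  fx <- tiny_raw()
  nr <- normalize_raw(fx$raw)
  expect_equal(max(Mod(gridded_recon(nr))), 1, tolerance = 1e-6)
  expect_gt(nr$norm_factor, 0)
  nr2 <- normalize_raw(nr)
  expect_equal(nr2$norm_factor / nr$norm_factor, 1, tolerance = 1e-6)
  zero <- fx$raw; zero$samples[] <- 0
  expect_error(normalize_raw(zero), "all-zero")
})

test_that("unregularized k-t reconstruction solves the least-squares problem", {
  fx <- tiny_raw()
  raw <- fx$raw
  bins <- rep(0L, nrow(raw$schedule))
  kt <- kt_sparse_sense(raw, bins, recon_config(0, 0, n_iterations = 1500,
                                                tolerance = 0),
                        n_phases = 1L)
  expect_true(all(diff(kt$objective) <= 0))
  # independent least-squares oracle from the explicit DFT matrix
  E <- explicit_dft_matrix(raw)
  A <- rbind(E %*% diag(as.vector(raw$coils[, , 1])),
             E %*% diag(as.vector(raw$coils[, , 2])))
  y <- c(as.vector(t(raw$samples[, , 1])), as.vector(t(raw$samples[, , 2])))
  xls <- qr.solve(Conj(t(A)) %*% A, Conj(t(A)) %*% y)
  nrmse <- sqrt(sum(Mod(as.vector(kt$images) - xls)^2) / sum(Mod(xls)^2))
  expect_lt(nrmse, 0.01)
})

test_that("temporal regularization beats gridding on undersampled dynamics", {
  ph <- make_phantom(phantom_config(grid_size = 32, voxel_mm = 2,
                                    resp_amplitude_mm = c(0, 0, 0),
                                    vessel_radius_mm = 6))
  cfg <- sequence_config("FISS", mode = "2d", n_interleaves = 10, fov_mm = 64,
                         resolution_mm = 2, oversampling = 1)
  sched <- build_schedule(cfg, 0)
  coils <- make_coil_maps(2, 32, 2, seed = 3)
  raw <- simulate_scan(ph, sched, coils, noise_sd = 0)
  trig <- true_triggers(ph, range(sched$t) + c(-0.1, 0.9))
  bins <- assign_cardiac_phase(sched$t, trig, 4L)
  raw <- normalize_raw(raw)
  kt <- kt_sparse_sense(raw, bins, recon_config(0.03, 0.015,
                                                n_iterations = 25),
                        n_phases = 4L)
  grid_ph <- gridded_recon(raw, bins, n_phases = 4L)
  # scalar-calibrated NRMSE against the rendered ground truth per phase
  rr <- 1 / ph$config$heart_rate_hz
  nrmse <- function(est) {
    tot <- 0; ref <- 0
    for (p in 1:4) {
      truth <- render_frame(ph, (p - 0.5) / 4 * rr, "FISS", apply_resp = FALSE)
      x <- Mod(est[, , p])
      a <- sum(x * truth) / sum(x^2)
      tot <- tot + sum((a * x - truth)^2); ref <- ref + sum(truth^2)
    }
    sqrt(tot / ref)
  }
  expect_lt(nrmse(kt$images), nrmse(grid_ph))
})

test_that("balanced 4-point decoding inverts the encoding exactly", {
  venc <- 150
  H <- venc_encoding_matrix()
  # all segments identical: zero velocity
  same <- lapply(1:4, function(s) array(1 + 2i, c(4, 4, 2)))
  expect_true(all(decode_velocity(same, venc)$velocity == 0))
  # printed convention case: phases (pi/2)(-1, 1, 1, -1) -> (venc, 0, 0)
  segs <- lapply(c(-1, 1, 1, -1), function(s)
    array(exp(1i * s * pi / 2), c(2, 2, 1)))
  v <- decode_velocity(segs, venc)$velocity
  expect_equal(as.vector(v[1, 1, 1, ]), c(venc, 0, 0), tolerance = 1e-9)
  # encode -> decode round trip for random |v| < venc, exact to 1e-6 cm/s
  set.seed(5)
  vr <- matrix(runif(900, -1, 1), 300, 3)
  vr <- vr * runif(300, 0, venc * 0.999) / sqrt(rowSums(vr^2))
  phs <- (pi / (2 * venc)) * vr %*% t(H)
  segs <- lapply(1:4, function(s) array(exp(1i * phs[, s]), c(30, 10, 1)))
  dec <- decode_velocity(segs, venc)
  expect_lt(max(abs(matrix(dec$velocity, 300, 3) - vr)), 1e-6)
  # mismatched grids rejected
  bad <- same; bad[[4]] <- array(1, c(3, 3, 2))
  expect_error(decode_velocity(bad, venc), "mismatch")
})

test_that("the combination keeps FISS magnitude and PC velocity bitwise", {
  mag <- array(runif(32), c(4, 4, 2))
  vel <- array(rnorm(96), c(4, 4, 2, 3))
  pcmag <- array(runif(32), c(4, 4, 2))
  fiss <- cine4d(mag, 2, rr_s = 0.8)
  flow <- flow4d(vel, pcmag, 150, 2, rr_s = 0.8)
  syn <- combine_synaps(fiss, flow)
  expect_identical(syn$magnitude, mag)
  expect_identical(syn$velocity, vel)
  # the native and combined pathways share identical velocity arrays
  expect_identical(syn$velocity, flow$velocity)
  # phase-count mismatch is an error, not a resample
  flow10 <- flow4d(array(0, c(4, 4, 5, 3)), array(0, c(4, 4, 5)), 150, 2)
  expect_error(combine_synaps(fiss, flow10), "phase counts")
})
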