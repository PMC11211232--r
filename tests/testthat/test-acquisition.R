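test_that("coil maps are smooth and sum-of-squares normalized", {
  one <- make_coil_maps(1, 16, 2)
  expect_true(all(one == 1 + 0i))
  maps <- make_coil_maps(4, 32, 2, seed = 9)
  sos <- apply(abs(maps)^2, c(1, 2), sum)
  expect_true(all(abs(sos - 1) < 1e-6))
  expect_identical(unclass(maps), unclass(make_coil_maps(4, 32, 2, seed = 9)))
})

test_that("balanced 4-point encoding matrix satisfies t(H) H = 4 I", {
  H <- venc_encoding_matrix()
  expect_identical(t(H) %*% H, diag(3) * 4)
})

test_that("encode_readout applies encoding phase and Fourier shifts", {
  n <- 16
  frame <- matrix(1, n, n)
  coils <- make_coil_maps(1, n, 2)
  k <- readout_kspace(c(0, 1, 0), 16, 0.25)
  # zero velocity: all four segments identical
  v0 <- array(0, c(n, n, 3))
  s_ref <- encode_readout(frame, v0, 0L, k, coils, venc = 150, voxel_mm = 2)
  for (seg in 1:3) {
    expect_equal(encode_readout(frame, v0, seg, k, coils, venc = 150,
                                voxel_mm = 2), s_ref, tolerance = 1e-12)
  }
  # uniform v_y = venc: paired-segment phase difference is pi at every voxel,
  # read off the k = 0 sample (segments 0 and 1 differ in h_y by 2)
  vy <- array(0, c(n, n, 3)); vy[, , 2] <- 150
  k0 <- which(rowSums(abs(k)) == 0)
  s0 <- encode_readout(frame, vy, 0L, k, coils, venc = 150, voxel_mm = 2)
  s1 <- encode_readout(frame, vy, 1L, k, coils, venc = 150, voxel_mm = 2)
  expect_equal(Arg(s1[k0, 1] / s0[k0, 1]), pi, tolerance = 1e-9)
  # shift theorem: 2 mm along y multiplies by exp(-2 pi i k_y * 2)
  sh <- encode_readout(frame, NULL, NA, k, coils, shift_mm = c(0, 2, 0),
                       voxel_mm = 2)
  un <- encode_readout(frame, NULL, NA, k, coils, voxel_mm = 2)
  expect_equal(sh[, 1], un[, 1] * exp(-2i * pi * k[, 2] * 2),
               tolerance = 1e-12)
  # out-of-band coordinates rejected
  expect_error(encode_readout(frame, NULL, NA, 2 * k, coils, voxel_mm = 2),
               "Nyquist")
})

test_that("simulated scans have schedule-shaped data and repeat determinism", {
  fx <- tiny_raw()
  expect_equal(dim(fx$raw$samples)[1], nrow(fx$raw$schedule))
  # readouts sharing direction and motion state produce identical data
  ph <- fx$phantom
  cfg <- sequence_config("FISS", mode = "2d", n_interleaves = 1,
                         fov_mm = 32, resolution_mm = 2, oversampling = 1)
  sched <- build_schedule(cfg, 0)
  sched[2, c("dir_x", "dir_y", "dir_z")] <- sched[1, c("dir_x", "dir_y", "dir_z")]
  coils <- make_coil_maps(2, 16, 2, seed = 3)
  raw <- simulate_scan(ph, sched, coils, noise_sd = 0, n_cardiac_states = 1L)
  expect_equal(raw$samples[1, , ], raw$samples[2, , ], tolerance = 1e-12)
  # PC schedule product shape
  pc <- sequence_config("PC", mode = "2d", n_interleaves = 10, fov_mm = 32,
                        resolution_mm = 2, oversampling = 1)
  sp <- build_schedule(pc, 0)
  expect_equal(nrow(sp), 210)
})

test_that("forward and adjoint NUDFT form an exact operator pair", {
  fx <- tiny_raw()
  raw <- fx$raw
  g <- synaps4d:::acq_geometry(raw)
  E <- explicit_dft_matrix(raw)
  nvox <- ncol(E)
  set.seed(11)
  x <- complex(real = rnorm(nvox), imaginary = rnorm(nvox))
  y <- matrix(complex(real = rnorm(nrow(E)), imaginary = rnorm(nrow(E))),
              g$rs$ns)
  Ax <- synaps4d:::radial_nudft_forward(cbind(x), g$coords, g$dirs,
                                        integer(nrow(raw$schedule)),
                                        g$rs$dk, g$rs$ns)
  Aty <- synaps4d:::radial_nudft_adjoint(y, g$coords, g$dirs, g$rs$dk, g$rs$ns)
  # matches the explicit DFT matrix
  expect_lt(max(Mod(as.vector(Ax) - as.vector(E %*% x))), 1e-8)
  expect_lt(max(Mod(Aty - as.vector(Conj(t(E)) %*% as.vector(y)))), 1e-8)
  # inner-product adjoint identity within 1e-8 relative
  ip1 <- sum(Conj(as.vector(Ax)) * as.vector(y))
  ip2 <- sum(Conj(x) * Aty)
  expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-8)
})
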