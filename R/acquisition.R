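#' Balanced 4-point velocity-encoding matrix
#'
#' Rows are the encoding vectors h_0..h_3 of the balanced (Hadamard-type)
#' 4-point scheme; each segment applies the voxelwise phase
#' `phi_seg = (pi / (2 * venc)) * (h_seg . v)` so that paired-segment phase
#' differences reach pi when one velocity component equals venc. The matrix
#' satisfies `t(H) %*% H = 4 * I`.
#'
#' @return 4 x 3 numeric matrix.
#' @export
venc_encoding_matrix <- function() {
  matrix(c(-1, -1, -1,
           1,  1, -1,
           1, -1,  1,
           -1,  1,  1), 4, 3, byrow = TRUE)
}

# Voxelwise encoding phase (radians) for one segment.
encoding_phase <- function(velocity, segment, venc) {
  h <- venc_encoding_matrix()[segment + 1L, ]
  (pi / (2 * venc)) * (h[1] * velocity[, , 1] + h[2] * velocity[, , 2] +
                         h[3] * velocity[, , 3])
}

#' Simulated coil sensitivity maps
#'
#' Smooth complex sensitivities (Gaussian-lobe magnitude around the field of
#' view, low-order polynomial phase), normalized so the voxelwise sum of
#' squared magnitudes is exactly 1. A single coil yields a uniform
#' unit-magnitude map.
#'
#' @param n_coils number of coils (>= 1).
#' @param grid grid size (voxels per axis).
#' @param voxel_mm voxel size (mm).
#' @param seed RNG seed for the lobe placement jitter.
#' @return complex array (grid, grid, n_coils) of class `coil_maps`.
#' @export
make_coil_maps <- function(n_coils, grid, voxel_mm = 2.0, seed = 1L) {
  if (n_coils < 1) stopf("n_coils must be >= 1")
  n <- as.integer(grid)
  if (n_coils == 1) {
    maps <- array(1 + 0i, c(n, n, 1))
    class(maps) <- "coil_maps"
    return(maps)
  }
  fov <- n * voxel_mm
  ax <- axis_coords_mm(n, voxel_mm)
  yy <- matrix(ax, n, n)
  zz <- matrix(ax, n, n, byrow = TRUE)
  maps <- with_seed(seed, {
    out <- array(0 + 0i, c(n, n, n_coils))
    ang0 <- runif(1, 0, 2 * pi)
    for (c in seq_len(n_coils)) {
      ang <- ang0 + 2 * pi * (c - 1) / n_coils
      cy <- 0.55 * fov / 2 * cos(ang) + rnorm(1, 0, 0.02 * fov)
      cz <- 0.55 * fov / 2 * sin(ang) + rnorm(1, 0, 0.02 * fov)
      mag <- exp(-((yy - cy)^2 + (zz - cz)^2) / (2 * (0.6 * fov)^2))
      ph <- runif(1, -pi, pi) +
        runif(1, -1, 1) * pi * yy / fov + runif(1, -1, 1) * pi * zz / fov +
        runif(1, -0.3, 0.3) * pi * (yy * zz) / fov^2
      out[, , c] <- mag * exp(1i * ph)
    }
    out
  })
  sos <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / sos
  class(maps) <- "coil_maps"
  maps
}

#' Encode one readout
#'
#' Multi-coil k-space samples of an image frame along one readout:
#' `s_c(k) = NUDFT{ S_c * frame * exp(i phi_enc) }(k) * exp(-i 2 pi k .
#' shift)`, with the velocity-encoding phase of the requested balanced
#' 4-point segment (or zero when `enc_segment` is `NA`) and a rigid
#' displacement applied through the Fourier shift theorem.
#'
#' @param frame real image matrix (y, z).
#' @param velocity velocity array (y, z, 3) in cm/s, or NULL.
#' @param enc_segment encoding segment 0..3, or `NA` for no encoding.
#' @param kcoords k-space sample coordinates (N x 3, cycles/mm), e.g. from
#'   [readout_kspace()].
#' @param coils [make_coil_maps()] array.
#' @param shift_mm rigid displacement 3-vector (mm).
#' @param venc velocity-encoding limit (cm/s); required when encoding.
#' @param voxel_mm voxel size (mm).
#' @return complex matrix N x n_coils.
#' @export
encode_readout <- function(frame, velocity = NULL, enc_segment = NA,
                           kcoords, coils, shift_mm = c(0, 0, 0),
                           venc = NA, voxel_mm = 2.0) {
  n <- nrow(frame)
  if (max(abs(kcoords)) > 1 / (2 * voxel_mm) + 1e-12) {
    stopf("k-space coordinate outside the Nyquist band 1/(2 * %.2f mm)", voxel_mm)
  }
  img <- frame + 0i
  if (!is.na(enc_segment)) {
    if (is.null(velocity) || is.na(venc)) {
      stopf("velocity field and venc required for encoding segment %d", enc_segment)
    }
    stopifnot(all(dim(velocity)[1:2] == dim(frame)))
    img <- img * exp(1i * encoding_phase(velocity, enc_segment, venc))
  }
  coords <- grid_coords_mm(n, voxel_mm, "2d")
  phase <- exp(-2i * pi * (kcoords %*% t(coords)))  # N x nvox
  shift_fac <- exp(-2i * pi * drop(kcoords %*% shift_mm))
  ncoil <- dim(coils)[3]
  out <- matrix(0 + 0i, nrow(kcoords), ncoil)
  for (c in seq_len(ncoil)) {
    out[, c] <- (phase %*% as.vector(coils[, , c] * img)) * shift_fac
  }
  out
}

#' Simulate a free-running acquisition
#'
#' Runs a readout schedule against the dynamic phantom: every readout
#' encodes the phantom frozen at its own timestamp (cardiac state quantized
#' to `n_cardiac_states` rendered frames), the respiratory displacement
#' `c_true * r(t)` enters as a linear k-space phase, complex Gaussian noise
#' is added, and a pilot-tone record spanning the schedule is attached.
#'
#' @param phantom a [make_phantom()] object.
#' @param schedule a [build_schedule()] data frame.
#' @param coils coil maps matching the phantom grid.
#' @param noise_sd complex noise standard deviation (a.u.).
#' @param n_cardiac_states number of quantized cardiac motion states.
#' @param pt optional pre-simulated pilot-tone record (shared across
#'   back-to-back sequences); when NULL one is simulated over the schedule
#'   span.
#' @param pt_noise_sd,pt_drift_per_min pilot-tone simulation parameters used
#'   when `pt` is NULL.
#' @param seed RNG seed for the noise (defaults to the phantom seed).
#' @return object of class `raw_acquisition` with fields `samples`
#'   (readout x sample x coil), `schedule`, `coils`, `pt`, `meta`, `grid`
#'   and a ground-`truth` block.
#' @export
simulate_scan <- function(phantom, schedule, coils, noise_sd = 0,
                          n_cardiac_states = 64L, pt = NULL,
                          pt_noise_sd = 0.1, pt_drift_per_min = 0.5,
                          seed = phantom$config$seed) {
  cfg <- attr(schedule, "config")
  pcfg <- phantom$config
  if (abs(cfg$fov_mm - pcfg$fov_mm) > 1e-9) {
    stopf("sequence FOV %.1f mm does not match phantom FOV %.1f mm",
          cfg$fov_mm, pcfg$fov_mm)
  }
  n <- pcfg$grid_size
  rs <- radial_samples(cfg)
  coords <- grid_coords_mm(n, pcfg$voxel_mm, pcfg$mode)
  dirs <- as.matrix(schedule[, c("dir_x", "dir_y", "dir_z")])
  nro <- nrow(schedule)

  # quantized cardiac states actually used by this schedule
  phase <- phantom$cardiac_phase_fn(schedule$t)
  state_of_ro <- pmin(floor(phase * n_cardiac_states), n_cardiac_states - 1L)
  used <- sort(unique(state_of_ro))
  state_t <- (used + 0.5) / n_cardiac_states / pcfg$heart_rate_hz

  contrast <- if (cfg$name == "FISS") "FISS" else "PC"
  segs <- if (cfg$name == "PC") c(NA, 0:3) else NA
  # image column lookup: key = state index * 5 + segment slot
  col_key <- integer(0)
  imgs <- NULL
  cols <- list()
  for (si in seq_along(used)) {
    fr <- render_frame(phantom, state_t[si], contrast, apply_resp = FALSE)
    vel <- if (cfg$name == "PC") {
      render_velocity(phantom, state_t[si], apply_resp = FALSE)
    } else NULL
    for (sg in segs) {
      img <- fr + 0i
      if (!is.na(sg)) img <- img * exp(1i * encoding_phase(vel, sg, cfg$venc_cm_s))
      cols[[length(cols) + 1L]] <- as.vector(img)
      col_key <- c(col_key, used[si] * 5L + (if (is.na(sg)) 0L else sg + 1L))
    }
  }
  imgs <- do.call(cbind, cols)

  seg_slot <- ifelse(is.na(schedule$segment), 0L, schedule$segment + 1L)
  ro_key <- state_of_ro * 5L + seg_slot
  col_of_ro <- match(ro_key, col_key) - 1L  # 0-based for C++

  # respiratory displacement per readout
  disp <- resp_displacement(phantom, schedule$t)  # nro x 3
  proj <- rowSums(dirs * disp)                    # dir . shift (mm)
  shift_phase <- exp(-2i * pi * outer(rs$t, proj))  # ns x nro

  ncoil <- dim(coils)[3]
  samples <- array(0 + 0i, c(rs$ns, nro, ncoil))
  for (c in seq_len(ncoil)) {
    imc <- imgs * as.vector(coils[, , c])
    y <- radial_nudft_forward(imc, coords, dirs, as.integer(col_of_ro),
                              rs$dk, rs$ns)
    samples[, , c] <- y * shift_phase
  }
  if (noise_sd > 0) {
    samples <- samples + with_seed(derive_seed(seed, 11L), {
      array(complex(real = rnorm(length(samples), 0, noise_sd / sqrt(2)),
                    imaginary = rnorm(length(samples), 0, noise_sd / sqrt(2))),
            dim(samples))
    })
  }
  samples <- aperm(samples, c(2, 1, 3))  # readout x sample x coil

  if (is.null(pt)) {
    pt <- simulate_pt(phantom, schedule_end(schedule), noise_sd = pt_noise_sd,
                      drift_per_min = pt_drift_per_min, seed = seed)
  }

  raw <- structure(list(
    samples = samples, schedule = schedule, coils = coils, pt = pt,
    meta = cfg,
    grid = list(n = n, voxel_mm = pcfg$voxel_mm, mode = pcfg$mode),
    truth = list(
      c_true_mm = pcfg$resp_amplitude_mm,
      trigger_times = true_triggers(phantom, range(schedule$t)),
      stroke_volume_ml = pcfg$stroke_volume_ml,
      phantom_config = pcfg
    ),
    norm_factor = 1
  ), class = "raw_acquisition")
  raw
}

#' @export
print.raw_acquisition <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("Raw %s acquisition: %d readouts x %d samples x %d coils (%s, %d voxel grid)\n",
              x$meta$name, d[1], d[2], d[3], x$grid$mode, x$grid$n))
  invisible(x)
}
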