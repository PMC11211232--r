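#' Default tissue contrast table
#'
#' Relative steady-state signal intensities of the phantom tissues under the
#' two simulated contrast mechanisms. FISS gives bright blood with inherent
#' fat suppression and a blood/myocardium ratio of 1.5; the phase-contrast
#' (PC) readout has low blood signal (ratio 0.7 against myocardium) and
#' bright fat, emulating the low blood-to-myocardium contrast that motivates
#' borrowing the anatomical magnitude from the FISS acquisition.
#'
#' @return data.frame with columns `tissue`, `fiss`, `pc`.
#' @export
default_contrast_table <- function() {
  data.frame(
    tissue = c("background", "soft_tissue", "fat", "myocardium", "blood"),
    fiss = c(0, 0.8, 0, 2.0, 3.0),
    pc = c(0, 1.0, 1.8, 2.0, 1.4),
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' Parameters of the dynamic beating/breathing torso phantom. The respiratory
#' amplitude vector is the ground truth for the fNAV displacement
#' coefficients (mm along x, y, z); in 2D mode the slice plane is (y, z) so
#' the superior-inferior z component is in-plane and recoverable, while x is
#' the through-plane flow direction.
#'
#' @param grid_size voxels per axis (>= 16).
#' @param mode "2d" (single slice, through-plane flow; default test scale) or
#'   "3d".
#' @param voxel_mm isotropic voxel size in mm.
#' @param heart_rate_hz cardiac frequency (Hz).
#' @param resp_rate_hz respiratory frequency (Hz).
#' @param resp_amplitude_mm length-3 maximum respiratory displacement (mm),
#'   the ground-truth fNAV coefficients; each component within +/- 25 mm.
#' @param stroke_volume_ml volume ejected per beat through each vessel (mL).
#' @param vessel_radius_mm end-diastolic vessel radius (mm); must stay below
#'   a quarter of the field of view.
#' @param vessel_area_pulsatility fractional systolic increase of the vessel
#'   cross-sectional area.
#' @param systole_fraction fraction of the RR interval occupied by the
#'   raised-cosine systolic flow pulse.
#' @param resp_shape_power exponent of the raised-cosine breathing waveform;
#'   values > 1 lengthen the end-expiratory plateau (asymmetric, as in free
#'   breathing) which also makes the curve's polarity identifiable.
#' @param contrast_table tissue intensity table, see
#'   [default_contrast_table()].
#' @param seed integer seed controlling every random element derived from the
#'   phantom.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_size = 64,
                           mode = c("2d", "3d"),
                           voxel_mm = 2.0,
                           heart_rate_hz = 1.2,
                           resp_rate_hz = 0.25,
                           resp_amplitude_mm = c(0, 0, 8),
                           stroke_volume_ml = 25,
                           vessel_radius_mm = 10,
                           vessel_area_pulsatility = 0.10,
                           systole_fraction = 0.35,
                           resp_shape_power = 2,
                           contrast_table = default_contrast_table(),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (grid_size < 16) stopf("grid_size must be >= 16, got %d", grid_size)
  if (length(resp_amplitude_mm) != 3 || any(abs(resp_amplitude_mm) > 25)) {
    stopf("resp_amplitude_mm must be a 3-vector within +/- 25 mm")
  }
  if (stroke_volume_ml <= 0) stopf("stroke_volume_ml must be > 0")
  fov <- grid_size * voxel_mm
  if (vessel_radius_mm >= fov / 4) {
    stopf("vessel radius %.1f mm >= FOV/4 (%.1f mm): invalid geometry",
          vessel_radius_mm, fov / 4)
  }
  if (heart_rate_hz <= 0 || resp_rate_hz <= 0) stopf("rates must be positive")
  structure(list(
    grid_size = as.integer(grid_size), mode = mode, voxel_mm = voxel_mm,
    heart_rate_hz = heart_rate_hz, resp_rate_hz = resp_rate_hz,
    resp_amplitude_mm = as.numeric(resp_amplitude_mm),
    stroke_volume_ml = stroke_volume_ml, vessel_radius_mm = vessel_radius_mm,
    vessel_area_pulsatility = vessel_area_pulsatility,
    systole_fraction = systole_fraction, resp_shape_power = resp_shape_power,
    contrast_table = contrast_table, seed = as.integer(seed),
    fov_mm = fov
  ), class = "phantom_config")
}

# Raised-cosine systolic pulse on cardiac phase in [0,1): unit peak in the
# first `systole_fraction` of the RR interval, zero in diastole.
cardiac_pulse <- function(phase, systole_fraction) {
  p <- phase %% 1
  ifelse(p < systole_fraction,
         (1 - cos(2 * pi * p / systole_fraction)) / 2, 0)
}

#' Build a dynamic phantom
#'
#' Assembles the torso geometry (soft-tissue ellipse, peripheral fat layer,
#' myocardial shell with contracting blood pool, and two through-plane
#' vessels standing in for the ascending and descending aorta), the cardiac
#' and respiratory time functions, and the calibration of the pulsatile
#' velocity amplitude so that the flow-rate integral over one beat equals the
#' configured stroke volume.
#'
#' @param config a [phantom_config()].
#' @return object of class `synaps_phantom`.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  sc <- config$fov_mm / 128  # geometry designed at a 128 mm FOV

  geometry <- list(
    torso = list(center = c(0, 0), semi = c(54, 58) * sc),
    fat_frac = 0.88,  # fat layer between 0.88*torso and the torso boundary
    heart = list(center = c(-16, 6) * sc, r_outer = 17 * sc,
                 r_inner = 11 * sc, contraction = 0.25),
    vessels = list(  # well separated so the cross-sections stay distinct
      AAo = list(center = c(20, 16) * sc, flow_sign = +1),
      DAo = list(center = c(8, -26) * sc, flow_sign = -1)
    )
  )

  cfg <- config
  cardiac_phase_fn <- function(t) (t * cfg$heart_rate_hz) %% 1
  resp_curve_fn <- function(t) {
    b <- ((1 - cos(2 * pi * cfg$resp_rate_hz * t)) / 2)^cfg$resp_shape_power
    2 * b - 1
  }

  # Calibrate the peak on-axis velocity V so that one beat integrates to the
  # stroke volume: SV = int Q dt, Q = (vmax/2) * pi R(t)^2 (parabolic profile,
  # cm/s * mm^2 * 0.01 = mL/s), with the systolic area modulation included.
  rr <- 1 / cfg$heart_rate_hz
  ph <- (seq_len(4000) - 0.5) / 4000
  pulse <- cardiac_pulse(ph, cfg$systole_fraction)
  r2 <- cfg$vessel_radius_mm^2 * (1 + cfg$vessel_area_pulsatility * pulse)
  integral_per_unit_v <- sum(0.5 * pulse * pi * r2 * 0.01) * rr / 4000
  vmax_peak <- cfg$stroke_volume_ml / integral_per_unit_v

  structure(list(
    config = cfg, geometry = geometry,
    cardiac_phase_fn = cardiac_phase_fn,
    resp_curve_fn = resp_curve_fn,
    vmax_peak_cm_s = vmax_peak
  ), class = "synaps_phantom")
}

#' @export
print.synaps_phantom <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Dynamic phantom (%s, %d^%d grid, %.1f mm voxels)\n",
              cfg$mode, cfg$grid_size, if (cfg$mode == "2d") 2L else 3L,
              cfg$voxel_mm))
  cat(sprintf("  heart %.2f Hz, breathing %.2f Hz, amplitude (%s) mm\n",
              cfg$heart_rate_hz, cfg$resp_rate_hz,
              paste(cfg$resp_amplitude_mm, collapse = ", ")))
  cat(sprintf("  2 vessels, R = %.1f mm, stroke volume %.1f mL/beat, peak v %.1f cm/s\n",
              cfg$vessel_radius_mm, cfg$stroke_volume_ml, x$vmax_peak_cm_s))
  invisible(x)
}

# Vessel radius (mm) at a cardiac phase.
vessel_radius_at <- function(phantom, phase) {
  cfg <- phantom$config
  pulse <- cardiac_pulse(phase, cfg$systole_fraction)
  cfg$vessel_radius_mm * sqrt(1 + cfg$vessel_area_pulsatility * pulse)
}

# Peak (on-axis) vessel velocity (cm/s) at a cardiac phase.
vmax_at <- function(phantom, phase) {
  phantom$vmax_peak_cm_s *
    cardiac_pulse(phase, phantom$config$systole_fraction)
}

# True flow rate (mL/s) through one vessel at a cardiac phase.
true_flow_rate <- function(phantom, phase) {
  0.5 * vmax_at(phantom, phase) * pi * vessel_radius_at(phantom, phase)^2 * 0.01
}

# Respiratory displacement (mm, 3-vector rows) at times t.
resp_displacement <- function(phantom, t) {
  outer(phantom$resp_curve_fn(t), phantom$config$resp_amplitude_mm)
}

# Supersampled in-plane (y,z) coordinates for rasterization, plus the fold
# dimensions for box-averaging back to the acquisition grid.
super_grid <- function(n, voxel_mm, s) {
  base <- axis_coords_mm(n, voxel_mm)
  off <- ((seq_len(s) - 0.5) / s - 0.5) * voxel_mm
  sort(as.vector(outer(off, base, "+")))
}

# Box-average an (n*s) x (n*s) matrix down to n x n.
box_average <- function(m, s) {
  n <- nrow(m) / s
  dim(m) <- c(s, n, s, n)
  out <- apply(m, c(2, 4), sum) / s^2
  out
}

# Tissue label map on a supersampled (y,z) grid at cardiac phase `phase`,
# displaced by `disp` = c(dy, dz) mm. Returns an integer matrix with levels
# matching the contrast table rows.
tissue_map_2d <- function(phantom, phase, disp, s) {
  cfg <- phantom$config
  g <- phantom$geometry
  ax <- super_grid(cfg$grid_size, cfg$voxel_mm, s)
  yy <- matrix(ax, length(ax), length(ax)) - disp[1]
  zz <- matrix(ax, length(ax), length(ax), byrow = TRUE) - disp[2]

  lab <- matrix(1L, nrow(yy), ncol(yy))  # background
  te <- (yy / g$torso$semi[1])^2 + (zz / g$torso$semi[2])^2
  lab[te <= 1] <- 2L                                         # soft tissue
  lab[te <= 1 & te > g$fat_frac^2] <- 3L                     # fat layer
  hd <- sqrt((yy - g$heart$center[1])^2 + (zz - g$heart$center[2])^2)
  r_in <- g$heart$r_inner * (1 - g$heart$contraction *
                               cardiac_pulse(phase, cfg$systole_fraction))
  lab[hd <= g$heart$r_outer] <- 4L                           # myocardium
  lab[hd <= r_in] <- 5L                                      # blood pool
  rv <- vessel_radius_at(phantom, phase)
  for (v in g$vessels) {
    vd <- sqrt((yy - v$center[1])^2 + (zz - v$center[2])^2)
    lab[vd <= rv] <- 5L                                      # vessel blood
  }
  lab
}

#' Render a phantom image frame
#'
#' Rasterizes the phantom at time `t` under the requested contrast with
#' supersampled partial-volume edges. The respiratory translation
#' `c_true * r(t)` is applied by shifting the scene coordinates (disable with
#' `apply_resp = FALSE` to obtain the reference motion state used by the
#' k-space phase-shift motion model).
#'
#' @param phantom a [make_phantom()] object.
#' @param t time in seconds.
#' @param contrast "FISS" or "PC".
#' @param apply_resp apply the respiratory displacement.
#' @param supersample supersampling factor for edge rasterization.
#' @return numeric matrix (`grid_size` x `grid_size`, axes y and z).
#' @export
render_frame <- function(phantom, t, contrast = c("FISS", "PC"),
                         apply_resp = TRUE, supersample = 4L) {
  contrast <- match.arg(contrast)
  cfg <- phantom$config
  if (cfg$mode != "2d") stopf("render_frame currently rasterizes 2d phantoms; use render_volume for 3d")
  phase <- phantom$cardiac_phase_fn(t)
  disp <- if (apply_resp) resp_displacement(phantom, t)[1, 2:3] else c(0, 0)
  lab <- tissue_map_2d(phantom, phase, disp, supersample)
  col <- if (contrast == "FISS") phantom$config$contrast_table$fiss else
    phantom$config$contrast_table$pc
  img <- matrix(col[lab], nrow(lab), ncol(lab))
  box_average(img, supersample)
}

#' Render the phantom velocity field
#'
#' Three-component velocity (cm/s) at time `t`. Inside each vessel the
#' through-plane (x) component follows a parabolic profile
#' `v(rho) = vmax(t) (1 - (rho/R)^2)` along the vessel axis and is zero
#' elsewhere; the ascending and descending vessels carry opposite through-
#' plane signs. Partial-volume edges use the same supersampled rasterization
#' as [render_frame()].
#'
#' @inheritParams render_frame
#' @return array (`grid_size`, `grid_size`, 3) of velocities in cm/s.
#' @export
render_velocity <- function(phantom, t, apply_resp = TRUE, supersample = 4L) {
  cfg <- phantom$config
  if (cfg$mode != "2d") stopf("render_velocity currently supports 2d phantoms")
  phase <- phantom$cardiac_phase_fn(t)
  disp <- if (apply_resp) resp_displacement(phantom, t)[1, 2:3] else c(0, 0)
  ax <- super_grid(cfg$grid_size, cfg$voxel_mm, supersample)
  yy <- matrix(ax, length(ax), length(ax)) - disp[1]
  zz <- matrix(ax, length(ax), length(ax), byrow = TRUE) - disp[2]
  vmax <- vmax_at(phantom, phase)
  rv <- vessel_radius_at(phantom, phase)
  vx <- matrix(0, nrow(yy), ncol(yy))
  for (v in phantom$geometry$vessels) {
    rho2 <- (yy - v$center[1])^2 + (zz - v$center[2])^2
    inside <- rho2 <= rv^2
    vx[inside] <- v$flow_sign * vmax * (1 - rho2[inside] / rv^2)
  }
  n <- cfg$grid_size
  out <- array(0, c(n, n, 3))
  out[, , 1] <- box_average(vx, supersample)
  out
}

#' Ground-truth vessel mask
#'
#' Rasterized mask of one vessel at cardiac phase `phase` (respiration at the
#' reference state), using majority partial-volume voting on the supersampled
#' grid.
#'
#' @param phantom phantom object.
#' @param phase cardiac phase in `[0, 1)`.
#' @param vessel "AAo" or "DAo".
#' @param supersample supersampling factor.
#' @return logical matrix.
#' @export
true_vessel_mask <- function(phantom, phase, vessel = c("AAo", "DAo"),
                             supersample = 4L) {
  vessel <- match.arg(vessel)
  cfg <- phantom$config
  v <- phantom$geometry$vessels[[vessel]]
  ax <- super_grid(cfg$grid_size, cfg$voxel_mm, supersample)
  yy <- matrix(ax, length(ax), length(ax))
  zz <- matrix(ax, length(ax), length(ax), byrow = TRUE)
  rv <- vessel_radius_at(phantom, phase)
  inside <- (yy - v$center[1])^2 + (zz - v$center[2])^2 <= rv^2
  box_average(inside * 1, supersample) >= 0.5
}

# Pixel index (y, z) of a vessel centre on the acquisition grid.
vessel_center_pixel <- function(phantom, vessel) {
  cfg <- phantom$config
  v <- phantom$geometry$vessels[[vessel]]
  ax <- axis_coords_mm(cfg$grid_size, cfg$voxel_mm)
  c(which.min(abs(ax - v$center[1])), which.min(abs(ax - v$center[2])))
}

#' True cardiac trigger times
#'
#' Beat onsets (cardiac phase zero crossings) within a time interval.
#'
#' @param phantom phantom object.
#' @param t_range length-2 interval in seconds.
#' @return numeric vector of trigger times.
#' @export
true_triggers <- function(phantom, t_range) {
  rr <- 1 / phantom$config$heart_rate_hz
  k <- seq(ceiling(t_range[1] / rr), floor(t_range[2] / rr))
  k * rr
}

#' Simulate pilot-tone channel signals
#'
#' Each channel is a seeded linear mixture of the cardiac source (a sharp
#' negative deflection at every beat onset, so its local minima mark the
#' triggers) and the respiratory source `r(t)`, plus per-channel linear
#' drift, an optional step offset at the inter-sequence gap, and Gaussian
#' noise.
#'
#' @param phantom phantom object.
#' @param duration_s record duration in seconds (starting at t = 0).
#' @param n_channels number of receive channels (>= 2; default 12 matches a
#'   12-channel body coil array with an integrated pilot-tone generator).
#' @param fs sampling rate in Hz; must exceed twice the cardiac frequency.
#' @param noise_sd additive Gaussian noise standard deviation (a.u.).
#' @param drift_per_min linear drift scale (a.u. per minute).
#' @param gap_time optional time (s) of the inter-sequence acquisition
#'   interrupt; a per-channel step offset is added after it.
#' @param step_scale standard deviation of the per-channel step offset.
#' @param seed RNG seed (defaults to the phantom seed).
#' @return list with `data` (channels x time), `t`, `fs`, and the true
#'   `cardiac_source` / `resp_source` series.
#' @export
simulate_pt <- function(phantom, duration_s, n_channels = 12L, fs = 50,
                        noise_sd = 0.1, drift_per_min = 0.5,
                        gap_time = NULL, step_scale = 0.5,
                        seed = phantom$config$seed) {
  if (n_channels < 2) stopf("need at least 2 pilot-tone channels")
  if (fs <= 2 * phantom$config$heart_rate_hz) {
    stopf("PT sampling rate %.1f Hz too low for cardiac frequency %.2f Hz",
          fs, phantom$config$heart_rate_hz)
  }
  t <- seq(0, duration_s, by = 1 / fs)
  phase <- phantom$cardiac_phase_fn(t)
  # quasi-sinusoidal cardiac modulation with a mild second harmonic: one
  # minimum per cycle at the beat onset, sharper than the maximum (so the
  # trigger polarity is identifiable), dominated by its fundamental as PT
  # amplitude modulations are.
  s_card <- -cos(2 * pi * phase) - 0.2 * cos(4 * pi * phase)
  s_resp <- phantom$resp_curve_fn(t)
  with_seed(seed, {
    a_r <- runif(n_channels, 0.6, 1.4) * sample(c(-1, 1), n_channels, TRUE)
    a_c <- runif(n_channels, 0.2, 0.5) * sample(c(-1, 1), n_channels, TRUE)
    b <- runif(n_channels, -1, 1) * drift_per_min / 60
    step <- if (!is.null(gap_time)) rnorm(n_channels, 0, step_scale) else
      numeric(n_channels)
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n_channels * length(t), 0, noise_sd), n_channels)
    } else matrix(0, n_channels, length(t))
    data <- outer(a_r, s_resp) + outer(a_c, s_card) + outer(b, t) + noise
    if (!is.null(gap_time)) data <- data + outer(step, as.numeric(t > gap_time))
    list(data = data, t = t, fs = fs,
         cardiac_source = s_card, resp_source = s_resp,
         gap_time = gap_time)
  })
}
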