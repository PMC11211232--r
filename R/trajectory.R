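#' Sequence configuration
#'
#' Acquisition parameters of the two free-running 3D radial sequences. The
#' full-scale defaults follow the published protocol: FISS with 2000
#' interleaves of 24 readouts (6 modules x 4 readouts, TR 2.94 ms) and PC
#' with 4820 interleaves of 21 readouts (1 superior-inferior projection + 5
#' readout lines x 4-point velocity encoding, TR 5.3 ms, venc 150 cm/s), a
#' 220 mm field of view at 2.0 mm resolution with 2x readout oversampling.
#' Desk-scale simulations shrink `n_interleaves`, `fov_mm` and
#' `oversampling`.
#'
#' @param name "FISS" or "PC".
#' @param mode "2d" (golden-angle in-plane spokes) or "3d" (spiral
#'   phyllotaxis over the half-sphere).
#' @param n_interleaves number of interleaves.
#' @param tr_ms,te_ms repetition / echo time (ms).
#' @param venc_cm_s velocity-encoding limit (cm/s, PC only).
#' @param fov_mm field of view (mm).
#' @param resolution_mm spatial resolution (mm).
#' @param oversampling readout oversampling factor.
#' @param samples_per_readout samples per readout; defaults to
#'   `oversampling * fov_mm / resolution_mm` (must be even).
#' @return object of class `sequence_config`.
#' @export
sequence_config <- function(name = c("FISS", "PC"),
                            mode = c("3d", "2d"),
                            n_interleaves = NULL,
                            tr_ms = NULL, te_ms = NULL,
                            venc_cm_s = 150,
                            fov_mm = 220, resolution_mm = 2.0,
                            oversampling = 2,
                            samples_per_readout = NULL) {
  name <- match.arg(name)
  mode <- match.arg(mode)
  n_interleaves <- n_interleaves %||% if (name == "FISS") 2000L else 4820L
  tr_ms <- tr_ms %||% if (name == "FISS") 2.94 else 5.3
  te_ms <- te_ms %||% if (name == "FISS") 1.5 else 3.5
  readouts_per_interleave <- if (name == "FISS") 24L else 21L
  if (n_interleaves < 1) stopf("n_interleaves must be >= 1")
  if (name == "PC" && venc_cm_s <= 0) stopf("venc must be > 0")
  matrix_size <- fov_mm / resolution_mm
  if (abs(matrix_size - round(matrix_size)) > 1e-9) {
    stopf("fov_mm / resolution_mm must be integral (got %.3f)", matrix_size)
  }
  samples_per_readout <- samples_per_readout %||%
    as.integer(round(oversampling * matrix_size))
  if (samples_per_readout %% 2 != 0) stopf("samples_per_readout must be even")
  structure(list(
    name = name, mode = mode,
    n_interleaves = as.integer(n_interleaves),
    readouts_per_interleave = readouts_per_interleave,
    tr_ms = tr_ms, te_ms = te_ms,
    venc_cm_s = if (name == "PC") venc_cm_s else NA_real_,
    fov_mm = fov_mm, resolution_mm = resolution_mm,
    oversampling = oversampling,
    samples_per_readout = as.integer(samples_per_readout),
    kmax = 1 / (2 * resolution_mm)
  ), class = "sequence_config")
}

# Golden ratio and the azimuthal golden-angle increment 2*pi*(1 - 1/phi^2).
.golden <- (1 + sqrt(5)) / 2

#' Spiral phyllotaxis readout directions
#'
#' Unit direction vectors for `n_interleaves x readouts_per_interleave`
#' radial readouts. In 3D the points follow a golden-angle spiral
#' phyllotaxis over the half-sphere (azimuth increment `2*pi*(1 - 1/phi^2)`,
#' polar angle interleaved so consecutive readouts of one interleave sweep
#' the polar range); in 2D they are golden-angle spokes in the (y, z) plane.
#' With `si_flag`, the first readout of every interleave is forced to the
#' superior-inferior (+z) direction.
#'
#' @param n_interleaves,readouts_per_interleave schedule shape.
#' @param si_flag force the first readout of each interleave to +z.
#' @param mode "3d" or "2d".
#' @return matrix (`n_interleaves * readouts_per_interleave`) x 3 of unit
#'   vectors, ordered interleave-major (readout fastest).
#' @export
phyllotaxis_directions <- function(n_interleaves, readouts_per_interleave,
                                   si_flag = FALSE, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  if (n_interleaves < 1 || readouts_per_interleave < 1) {
    stopf("counts must be >= 1")
  }
  n <- as.integer(n_interleaves)
  m <- as.integer(readouts_per_interleave)
  total <- n * m
  # interleaved index: readout j of interleave i -> point j*n + i
  i <- rep(seq_len(n) - 1L, each = m)
  j <- rep(seq_len(m) - 1L, times = n)
  k <- j * n + i
  if (mode == "2d") {
    theta <- (k * pi / .golden) %% pi
    dirs <- cbind(x = 0, y = cos(theta), z = sin(theta))
  } else {
    pol <- (pi / 2) * sqrt(k / max(total - 1L, 1L))
    az <- k * 2 * pi * (1 - 1 / .golden^2)
    dirs <- cbind(x = sin(pol) * cos(az), y = sin(pol) * sin(az),
                  z = cos(pol))
  }
  if (si_flag) dirs[j == 0L, ] <- rep(c(0, 0, 1), each = n)
  dirs
}

#' Build a readout schedule
#'
#' Per-readout records of one free-running acquisition: interleave and
#' readout indices, unit readout direction, timestamp, velocity-encoding
#' segment and superior-inferior flag. FISS interleaves hold 24 readouts
#' grouped as 6 modules x 4 readouts without velocity encoding; PC
#' interleaves hold 1 SI projection followed by 5 readout lines, each
#' repeated 4 times with balanced 4-point encoding segments 0..3 sharing one
#' direction. Timestamps advance by `tr_ms` per readout from `start_time`.
#'
#' @param config a [sequence_config()].
#' @param start_time schedule start (s).
#' @return data.frame of class `readout_schedule` with attributes `config`
#'   and `start_time`.
#' @export
build_schedule <- function(config, start_time = 0) {
  stopifnot(inherits(config, "sequence_config"))
  n <- config$n_interleaves
  m <- config$readouts_per_interleave
  interleave <- rep(seq_len(n) - 1L, each = m)
  readout <- rep(seq_len(m) - 1L, times = n)

  if (config$name == "FISS") {
    dirs <- phyllotaxis_directions(n, m, si_flag = FALSE, mode = config$mode)
    segment <- rep(NA_integer_, n * m)
    is_si <- rep(FALSE, n * m)
    module <- readout %/% 4L
  } else {
    # 5 encoded readout lines per interleave; golden-angle/phyllotaxis over
    # the line slots, each line repeated for the 4 encoding segments.
    line_dirs <- phyllotaxis_directions(n, 5L, si_flag = FALSE,
                                        mode = config$mode)
    dirs <- matrix(0, n * m, 3)
    segment <- rep(NA_integer_, n * m)
    is_si <- readout == 0L
    dirs[is_si, ] <- rep(c(0, 0, 1), each = sum(is_si))
    enc <- !is_si
    line <- (readout[enc] - 1L) %/% 4L        # 0..4
    segment[enc] <- (readout[enc] - 1L) %% 4L  # 0..3
    dirs[enc, ] <- line_dirs[line * n + interleave[enc] + 1L, ]
    module <- rep(NA_integer_, n * m)
  }

  sched <- data.frame(
    interleave = interleave, readout = readout,
    dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
    t = start_time + (seq_len(n * m) - 1L) * config$tr_ms / 1000,
    segment = segment, is_si = is_si, module = module
  )
  attr(sched, "config") <- config
  attr(sched, "start_time") <- start_time
  class(sched) <- c("readout_schedule", "data.frame")
  sched
}

#' End time of a schedule (last readout timestamp + one TR)
#' @param schedule a [build_schedule()] data frame.
#' @return time in seconds.
#' @export
schedule_end <- function(schedule) {
  cfg <- attr(schedule, "config")
  max(schedule$t) + cfg$tr_ms / 1000
}

#' Radial k-space sample coordinates of one readout
#'
#' Samples the diameter `k_i = kmax * (2*i - N) / N * direction` for
#' `i = 0..N-1`: symmetric about, and including, k = 0.
#'
#' @param direction unit 3-vector.
#' @param samples number of samples N (even).
#' @param kmax maximum spatial frequency, `1 / (2 * resolution_mm)`
#'   (cycles/mm).
#' @return matrix N x 3 of k-space coordinates (cycles/mm).
#' @export
readout_kspace <- function(direction, samples, kmax) {
  if (samples %% 2 != 0) stopf("samples must be even")
  i <- seq_len(samples) - 1L
  outer(kmax * (2 * i - samples) / samples, as.numeric(direction))
}

# Radial sample offsets t_i (cycles/mm) shared by all readouts of a schedule,
# and their spacing dk.
radial_samples <- function(config) {
  ns <- config$samples_per_readout
  dk <- 2 * config$kmax / ns
  list(t = dk * (seq_len(ns) - 1L - ns / 2), dk = dk, ns = ns)
}
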