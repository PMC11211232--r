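#' Reconstruction configuration
#'
#' Regularization weights and solver controls for the k-t sparse SENSE
#' reconstruction, applied to data normalized to the maximum of a gridded
#' reconstruction. Published weights: FISS 0.03 (cardiac) / 0.015 (spatial);
#' PC 0.0075 (cardiac) / 0.015 (spatial).
#'
#' @param lambda_cardiac total-variation weight along the (cyclic) cardiac
#'   dimension.
#' @param lambda_spatial total-variation weight along the spatial
#'   dimensions.
#' @param n_iterations maximum accepted solver iterations.
#' @param tolerance relative objective-change stopping tolerance.
#' @param tv_epsilon smoothing constant of the absolute value,
#'   `psi(d) = sqrt(|d|^2 + eps)`.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(lambda_cardiac = 0.03, lambda_spatial = 0.015,
                         n_iterations = 30L, tolerance = 1e-5,
                         tv_epsilon = 1e-6) {
  if (lambda_cardiac < 0 || lambda_spatial < 0) stopf("lambdas must be >= 0")
  structure(list(lambda_cardiac = lambda_cardiac,
                 lambda_spatial = lambda_spatial,
                 n_iterations = as.integer(n_iterations),
                 tolerance = tolerance, tv_epsilon = tv_epsilon),
            class = "recon_config")
}

#' Default regularization weights per sequence
#' @param name "FISS" or "PC".
#' @param ... overrides passed to [recon_config()].
#' @export
default_recon_config <- function(name = c("FISS", "PC"), ...) {
  name <- match.arg(name)
  args <- list(...)
  args$lambda_cardiac <- args$lambda_cardiac %||%
    if (name == "FISS") 0.03 else 0.0075
  do.call(recon_config, args)
}

# Radial density-compensation weights: |k| ramp with the k = 0 weight
# replaced by half the first nonzero weight (deterministic centre handling).
density_weights <- function(t, dk) {
  w <- abs(t)
  w[w == 0] <- dk / 2
  w
}

# Extract coil c from a (sample x readout x coil) array as a matrix,
# keeping the matrix shape even for a single readout.
coil_slice <- function(y, c) {
  m <- y[, , c, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

# Internal geometry bundle shared by the reconstruction operators.
acq_geometry <- function(raw) {
  rs <- radial_samples(raw$meta)
  list(rs = rs,
       coords = grid_coords_mm(raw$grid$n, raw$grid$voxel_mm, raw$grid$mode),
       dirs = as.matrix(raw$schedule[, c("dir_x", "dir_y", "dir_z")]),
       n = raw$grid$n, ncoil = dim(raw$samples)[3])
}

#' Gridded (density-compensated adjoint) reconstruction
#'
#' `|k|`-ramp density compensation, adjoint NUDFT per coil, and coil
#' combination with conjugate sensitivities. With a phase assignment the
#' reconstruction is computed per cardiac phase, otherwise all readouts are
#' pooled.
#'
#' @param raw a `raw_acquisition`.
#' @param bins optional integer phase per readout (`NA` = discarded), e.g.
#'   from [assign_cardiac_phase()].
#' @param n_phases number of phases when `bins` is given.
#' @return complex matrix (y, z) when pooled, or array (y, z, P) per phase.
#' @export
gridded_recon <- function(raw, bins = NULL, n_phases = NULL) {
  if (length(raw$samples) == 0) stopf("empty acquisition")
  g <- acq_geometry(raw)
  w <- density_weights(g$rs$t, g$rs$dk)
  recon_subset <- function(idx) {
    if (length(idx) == 0) return(NULL)
    img <- 0
    y <- aperm(raw$samples[idx, , , drop = FALSE], c(2, 1, 3)) * w
    for (c in seq_len(g$ncoil)) {
      a <- radial_nudft_adjoint(coil_slice(y, c),
                                g$coords, g$dirs[idx, , drop = FALSE],
                                g$rs$dk, g$rs$ns)
      img <- img + Conj(as.vector(raw$coils[, , c])) * a
    }
    matrix(img, g$n, g$n)
  }
  if (is.null(bins)) return(recon_subset(seq_len(nrow(raw$schedule))))
  P <- n_phases %||% (max(bins, na.rm = TRUE) + 1L)
  out <- array(0 + 0i, c(g$n, g$n, P))
  for (p in seq_len(P) - 1L) {
    idx <- which(bins == p)
    if (length(idx) == 0) stopf("cardiac phase bin %d contains no readouts", p)
    out[, , p + 1L] <- recon_subset(idx)
  }
  out
}

#' Normalize an acquisition to its gridded-reconstruction maximum
#'
#' Divides the raw data by the maximum magnitude of a pooled gridded
#' reconstruction, so regularization weights are defined on a common scale.
#' The factor is recorded (cumulatively) in `$norm_factor` for
#' de-normalization.
#'
#' @param raw a `raw_acquisition`.
#' @return the scaled `raw_acquisition`.
#' @export
normalize_raw <- function(raw) {
  if (all(raw$samples == 0)) stopf("cannot normalize all-zero data")
  factor <- max(Mod(gridded_recon(raw)))
  raw$samples <- raw$samples / factor
  raw$norm_factor <- raw$norm_factor * factor
  raw
}

# Smoothed-TV value and gradient on X (nvox x P complex).
# Cardiac dimension cyclic; spatial first differences per phase.
tv_terms <- function(X, n, lt, ls, eps) {
  P <- ncol(X)
  val <- 0
  grad <- matrix(0 + 0i, nrow(X), P)
  if (lt > 0 && P > 1) {
    D <- X[, c(2:P, 1L), drop = FALSE] - X
    psi <- sqrt(Mod(D)^2 + eps)
    val <- val + lt * sum(psi)
    U <- lt * D / psi
    grad <- grad - U
    grad[, c(2:P, 1L)] <- grad[, c(2:P, 1L)] + U
  }
  if (ls > 0) {
    for (p in seq_len(P)) {
      xm <- matrix(X[, p], n, n)
      gm <- matrix(0 + 0i, n, n)
      dy <- xm[2:n, , drop = FALSE] - xm[1:(n - 1), , drop = FALSE]
      psy <- sqrt(Mod(dy)^2 + eps)
      val <- val + ls * sum(psy)
      uy <- ls * dy / psy
      gm[2:n, ] <- gm[2:n, ] + uy
      gm[1:(n - 1), ] <- gm[1:(n - 1), ] - uy
      dz <- xm[, 2:n, drop = FALSE] - xm[, 1:(n - 1), drop = FALSE]
      psz <- sqrt(Mod(dz)^2 + eps)
      val <- val + ls * sum(psz)
      uz <- ls * dz / psz
      gm[, 2:n] <- gm[, 2:n] + uz
      gm[, 1:(n - 1)] <- gm[, 1:(n - 1)] - uz
      grad[, p] <- grad[, p] + as.vector(gm)
    }
  }
  list(value = val, grad = grad)
}

#' k-t sparse SENSE reconstruction
#'
#' Minimizes `0.5 * sum_p ||E_p x_p - y_p||^2 + lambda_t TV_cardiac(x) +
#' lambda_s TV_spatial(x)` over cardiac-phase-resolved images, where `E_p`
#' is the coil-weighted NUDFT of the readouts binned to phase `p`, the
#' cardiac total variation is cyclic and both TV terms use a smoothed
#' absolute value. Solved by Polak-Ribiere nonlinear conjugate gradient
#' with a backtracking line search seeded at the exact minimizer of the
#' quadratic data term along the search direction, initialized from the
#' density-compensated adjoint; the objective trace is non-increasing by
#' construction.
#'
#' @param raw a (normalized, motion-corrected) `raw_acquisition`.
#' @param bins integer cardiac phase per readout (`NA` = discarded).
#' @param cfg a [recon_config()].
#' @param segment for PC data, the velocity-encoding segment (0..3) to
#'   reconstruct; `NULL` uses all non-encoded (FISS) readouts.
#' @param n_phases number of cardiac phases (defaults to `max(bins) + 1`).
#' @return list with `images` (complex array y, z, P), `objective` trace,
#'   `converged` flag and the configuration.
#' @export
kt_sparse_sense <- function(raw, bins, cfg = default_recon_config(raw$meta$name),
                            segment = NULL, n_phases = NULL) {
  g <- acq_geometry(raw)
  keep <- !raw$schedule$is_si & !is.na(bins)
  if (!is.null(segment)) {
    keep <- keep & !is.na(raw$schedule$segment) & raw$schedule$segment == segment
  } else if (raw$meta$name == "PC") {
    stopf("PC reconstruction requires a velocity-encoding segment")
  }
  P <- n_phases %||% (max(bins, na.rm = TRUE) + 1L)
  idx_p <- lapply(seq_len(P) - 1L, function(p) which(keep & bins == p))
  empty <- which(vapply(idx_p, length, integer(1)) == 0)
  if (length(empty)) stopf("cardiac phase bin %d contains no readouts", empty[1] - 1L)

  nvox <- g$n^2
  coilv <- vapply(seq_len(g$ncoil), function(c) as.vector(raw$coils[, , c]),
                  complex(nvox))
  dirs_p <- lapply(idx_p, function(i) g$dirs[i, , drop = FALSE])
  y_p <- lapply(idx_p, function(i) aperm(raw$samples[i, , , drop = FALSE], c(2, 1, 3)))
  zero_state <- lapply(idx_p, function(i) integer(length(i)))

  forward_p <- function(x, p) {
    out <- array(0 + 0i, c(g$rs$ns, length(idx_p[[p]]), g$ncoil))
    for (c in seq_len(g$ncoil)) {
      out[, , c] <- radial_nudft_forward(cbind(coilv[, c] * x), g$coords,
                                         dirs_p[[p]], zero_state[[p]],
                                         g$rs$dk, g$rs$ns)
    }
    out
  }
  adjoint_p <- function(res, p) {
    acc <- complex(nvox)
    for (c in seq_len(g$ncoil)) {
      acc <- acc + Conj(coilv[, c]) *
        radial_nudft_adjoint(coil_slice(res, c),
                             g$coords, dirs_p[[p]], g$rs$dk, g$rs$ns)
    }
    acc
  }

  # init: density-compensated adjoint, globally scaled by a least-squares fit
  w <- density_weights(g$rs$t, g$rs$dk)
  X <- vapply(seq_len(P), function(p) adjoint_p(y_p[[p]] * w, p), complex(nvox))
  fw <- lapply(seq_len(P), function(p) forward_p(X[, p], p))
  num <- sum(vapply(seq_len(P), function(p)
    Re(sum(Conj(fw[[p]]) * y_p[[p]])), numeric(1)))
  den <- sum(vapply(seq_len(P), function(p)
    sum(Mod(fw[[p]])^2), numeric(1)))
  alpha0 <- if (den > 0) num / den else 0
  X <- X * alpha0
  res <- lapply(seq_len(P), function(p) fw[[p]] * alpha0 - y_p[[p]])

  tv_value <- function(X) tv_terms(X, g$n, cfg$lambda_cardiac,
                                   cfg$lambda_spatial, cfg$tv_epsilon)$value
  data_value <- function(res)
    0.5 * sum(vapply(res, function(r) sum(Mod(r)^2), numeric(1)))
  f <- data_value(res) + tv_value(X)
  trace <- f
  converged <- FALSE
  g_prev <- NULL
  dir <- NULL

  for (it in seq_len(cfg$n_iterations)) {
    grad <- vapply(seq_len(P), function(p) adjoint_p(res[[p]], p), complex(nvox)) +
      tv_terms(X, g$n, cfg$lambda_cardiac, cfg$lambda_spatial,
               cfg$tv_epsilon)$grad
    if (is.null(dir)) {
      dir <- -grad
    } else {
      beta <- max(0, Re(sum(Conj(grad) * (grad - g_prev))) /
                    Re(sum(Conj(g_prev) * g_prev)))
      dir <- -grad + beta * dir
      if (Re(sum(Conj(dir) * (-grad))) <= 0) dir <- -grad  # restart
    }
    g_prev <- grad
    # quadratic data term along the direction: one forward pass suffices
    Ad <- lapply(seq_len(P), function(p) forward_p(dir[, p], p))
    a_quad <- sum(vapply(Ad, function(v) sum(Mod(v)^2), numeric(1)))
    b_quad <- sum(vapply(seq_len(P), function(p)
      Re(sum(Conj(Ad[[p]]) * res[[p]])), numeric(1)))
    d0 <- data_value(res)
    alpha <- if (a_quad > 0) -b_quad / a_quad else 0
    if (alpha <= 0) break
    accepted <- FALSE
    for (bt in 1:30) {
      fn <- d0 + alpha * b_quad + 0.5 * alpha^2 * a_quad +
        tv_value(X + alpha * dir)
      if (fn <= f) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break
    X <- X + alpha * dir
    res <- lapply(seq_len(P), function(p) res[[p]] + alpha * Ad[[p]])
    rel <- (f - fn) / max(abs(f), 1e-300)
    f <- fn
    trace <- c(trace, f)
    if (rel < cfg$tolerance) { converged <- TRUE; break }
  }

  list(images = array(X, c(g$n, g$n, P)), objective = trace,
       converged = converged, config = cfg, norm_factor = raw$norm_factor)
}

#' Decode balanced 4-point velocity encoding
#'
#' Recovers the three-directional velocity field from the four
#' per-segment reconstructions: with segment phases
#' `phi = (pi / (2 venc)) H v` (plus a common background phase), the
#' least-squares decode is `v = (2 venc / pi) t(H) phi / 4`. Phase wrapping
#' is resolved by searching integer 2 pi wrap candidates and keeping the
#' solution with velocity components inside `[-venc, venc]` and the
#' smallest common (background) phase; voxels that required nonzero wraps
#' are flagged.
#'
#' @param segments list of 4 complex arrays (y, z, P), encoding segments
#'   0..3.
#' @param venc velocity-encoding limit (cm/s).
#' @return list with `velocity` (y, z, P, 3; cm/s), `wrapped` logical
#'   array, and `magnitude` (mean segment magnitude).
#' @export
decode_velocity <- function(segments, venc) {
  if (length(segments) != 4) stopf("need exactly 4 encoding segments")
  d <- dim(segments[[1]])
  if (!all(vapply(segments, function(s) identical(dim(s), d), logical(1)))) {
    stopf("segment reconstructions have mismatched grids")
  }
  H <- venc_encoding_matrix()
  N <- prod(d)
  Psi <- vapply(segments, function(s) Arg(as.vector(s)), numeric(N))
  v0 <- (2 * venc / pi) * (Psi %*% H) / 4
  beta0 <- rowMeans(Psi)

  m_grid <- as.matrix(expand.grid(m0 = -1:1, m1 = -1:1, m2 = -1:1, m3 = -1:1))
  shifts <- venc * (m_grid %*% H)           # 81 x 3 velocity offsets
  dbeta <- (pi / 2) * rowSums(m_grid)
  best_score <- rep(Inf, N)
  best_idx <- rep(1L, N)
  # strict interior margin: wrap candidates that land exactly on the
  # +/- venc boundary (e.g. for constant-phase inputs) must not displace
  # the in-range solution
  tol <- venc * (1 - 1e-6)
  for (i in seq_len(nrow(m_grid))) {
    vm1 <- v0[, 1] + shifts[i, 1]
    vm2 <- v0[, 2] + shifts[i, 2]
    vm3 <- v0[, 3] + shifts[i, 3]
    viol <- pmax(abs(vm1) - tol, 0) + pmax(abs(vm2) - tol, 0) +
      pmax(abs(vm3) - tol, 0)
    score <- 1e6 * viol + abs(beta0 + dbeta[i]) +
      1e-9 * (vm1^2 + vm2^2 + vm3^2) / venc^2
    better <- score < best_score
    best_score[better] <- score[better]
    best_idx[better] <- i
  }
  vel <- v0 + shifts[best_idx, , drop = FALSE]
  wrapped <- rowSums(abs(m_grid))[best_idx] > 0
  mag <- Reduce(`+`, lapply(segments, Mod)) / 4
  list(velocity = array(vel, c(d, 3)),
       wrapped = array(wrapped, d),
       magnitude = array(mag, d))
}

#' Cardiac-phase-resolved magnitude (cine) volume
#'
#' @param magnitude nonnegative array (y, z, P).
#' @param voxel_mm voxel size (mm).
#' @param rr_s RR interval (s) represented by the P phases.
#' @param source label of the originating sequence.
#' @export
cine4d <- function(magnitude, voxel_mm, rr_s = NA, source = "FISS") {
  if (any(magnitude < 0)) stopf("magnitudes must be nonnegative")
  structure(list(magnitude = magnitude, voxel_mm = voxel_mm,
                 n_phases = dim(magnitude)[3], rr_s = rr_s, source = source),
            class = "cine4d")
}

#' Phase-resolved velocity (4D flow) volume
#'
#' @param velocity array (y, z, P, 3) in cm/s.
#' @param magnitude companion magnitude array (y, z, P).
#' @param venc velocity-encoding limit (cm/s).
#' @param voxel_mm voxel size (mm).
#' @param rr_s RR interval (s).
#' @param wrapped optional logical array of velocity-aliased voxels.
#' @export
flow4d <- function(velocity, magnitude, venc, voxel_mm, rr_s = NA,
                   wrapped = NULL) {
  structure(list(velocity = velocity, magnitude = magnitude, venc = venc,
                 voxel_mm = voxel_mm, n_phases = dim(velocity)[3],
                 rr_s = rr_s, wrapped = wrapped),
            class = "flow4d")
}

#' Combine anatomical magnitude with phase-contrast velocity
#'
#' Builds the synchronized 4D flow dataset: the magnitude images are taken
#' unchanged from the bright-blood FISS cine and the velocity images
#' unchanged from the PC flow reconstruction. The two parents must share the
#' cardiac phase grid and voxel grid exactly; no resampling is performed.
#'
#' @param fiss a [cine4d()] reconstruction.
#' @param flow a [flow4d()] reconstruction.
#' @return object of class `synaps_flow4d`.
#' @export
combine_synaps <- function(fiss, flow) {
  stopifnot(inherits(fiss, "cine4d"), inherits(flow, "flow4d"))
  if (fiss$n_phases != flow$n_phases) {
    stopf("cardiac phase counts differ (%d vs %d): cannot combine",
          fiss$n_phases, flow$n_phases)
  }
  if (!identical(dim(fiss$magnitude), dim(flow$magnitude)) ||
      abs(fiss$voxel_mm - flow$voxel_mm) > 1e-9) {
    stopf("voxel grids differ: cannot combine without resampling")
  }
  structure(list(magnitude = fiss$magnitude, velocity = flow$velocity,
                 venc = flow$venc, voxel_mm = flow$voxel_mm,
                 n_phases = flow$n_phases,
                 rr_s = flow$rr_s %||% fiss$rr_s,
                 provenance = list(magnitude = fiss$source %||% "FISS",
                                   velocity = "PC")),
            class = "synaps_flow4d")
}
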