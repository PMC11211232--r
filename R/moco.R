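#' Entropy of the gradient image
#'
#' Image-blur metric for autofocus motion correction: the gradient-magnitude
#' image (central differences) is computed over a region of interest,
#' normalized to a probability distribution `p_i = g_i / sum(g)`, and the
#' natural-log entropy `-sum(p_i log p_i)` is returned. Sharp images
#' concentrate gradient energy in few pixels and score low; motion blur
#' spreads it and scores high. A zero-gradient ROI returns `Inf`.
#'
#' @param image real matrix.
#' @param roi list with integer index vectors `y` and `z`, or NULL for the
#'   whole image.
#' @return scalar entropy (natural log).
#' @export
gradient_entropy <- function(image, roi = NULL) {
  n1 <- nrow(image); n2 <- ncol(image)
  gy <- matrix(0, n1, n2); gz <- matrix(0, n1, n2)
  gy[2:(n1 - 1), ] <- (image[3:n1, ] - image[1:(n1 - 2), ]) / 2
  gz[, 2:(n2 - 1)] <- (image[, 3:n2] - image[, 1:(n2 - 2)]) / 2
  g <- sqrt(gy^2 + gz^2)
  if (!is.null(roi)) {
    if (length(roi$y) == 0 || length(roi$z) == 0) stopf("empty ROI")
    if (min(roi$y) < 1 || max(roi$y) > n1 || min(roi$z) < 1 || max(roi$z) > n2) {
      stopf("ROI outside image")
    }
    g <- g[roi$y, roi$z, drop = FALSE]
  }
  s <- sum(g)
  if (s == 0) return(Inf)
  p <- g[g > 0] / s
  -sum(p * log(p))
}

# Default ROI: central box of half the field of view.
default_heart_roi <- function(n) {
  idx <- seq(floor(n / 4) + 1L, floor(3 * n / 4))
  list(y = idx, z = idx)
}

#' Construct a rigid respiratory motion model
#'
#' @param coeffs_mm displacement coefficients c = (c_x, c_y, c_z) in mm.
#' @param resp_values unitless respiratory curve sampled at the readout
#'   timestamps it will correct.
#' @param times the matching timestamps (s).
#' @param entropy,trace optional fit diagnostics.
#' @return object of class `motion_model`; the per-readout displacement is
#'   `d(t) = coeffs_mm * r(t)`.
#' @export
motion_model <- function(coeffs_mm, resp_values, times, entropy = NA,
                         trace = NULL) {
  if (length(coeffs_mm) != 3) stopf("coeffs_mm must have length 3")
  if (any(abs(coeffs_mm) > 25)) stopf("|coefficients| exceed the 25 mm search bound")
  structure(list(coeffs_mm = as.numeric(coeffs_mm),
                 resp_values = as.numeric(resp_values),
                 times = as.numeric(times),
                 entropy = entropy, trace = trace),
            class = "motion_model")
}

# Displacement (nro x 3, mm) of a motion model at given times.
model_displacement <- function(model, times) {
  r <- approx(model$times, model$resp_values, xout = times, rule = 2)$y
  outer(r, model$coeffs_mm)
}

#' Apply respiratory motion correction to raw k-space
#'
#' Multiplies every readout's samples by `exp(+i 2 pi k . d(t))`, the exact
#' inverse of the displacement phase accrued during acquisition. Schedule,
#' coil maps and pilot-tone record are unchanged; applying the negated model
#' restores the input.
#'
#' @param raw a `raw_acquisition`.
#' @param model a [motion_model()] defined on the raw timestamps.
#' @return corrected `raw_acquisition` (with the model stored in `$moco`).
#' @export
apply_respiratory_correction <- function(raw, model) {
  stopifnot(inherits(raw, "raw_acquisition"), inherits(model, "motion_model"))
  sched <- raw$schedule
  d <- model_displacement(model, sched$t)
  if (nrow(d) != nrow(sched)) stopf("motion model / schedule length mismatch")
  if (any(d != 0)) {
    rs <- radial_samples(raw$meta)
    dirs <- as.matrix(sched[, c("dir_x", "dir_y", "dir_z")])
    proj <- rowSums(dirs * d)
    phase <- exp(2i * pi * outer(proj, rs$t))  # readout x sample
    for (c in seq_len(dim(raw$samples)[3])) {
      raw$samples[, , c] <- raw$samples[, , c] * phase
    }
  }
  raw$moco <- model
  raw
}

# Prepared context for repeated fNAV objective evaluations. `stride`
# subsamples the readouts of the pooled inner reconstruction; golden-angle
# subsets retain near-uniform angular coverage, so the entropy surrogate is
# evaluated on a fraction of the data.
fnav_context <- function(raw, resp_values, roi, stride = 1L) {
  rs <- radial_samples(raw$meta)
  keep <- seq(1, nrow(raw$schedule), by = stride)
  sched <- raw$schedule[keep, ]
  n <- raw$grid$n
  list(
    rs = rs,
    dirs = as.matrix(sched[, c("dir_x", "dir_y", "dir_z")]),
    coords = grid_coords_mm(n, raw$grid$voxel_mm, raw$grid$mode),
    # density-compensated samples, sample x readout x coil
    y = aperm(raw$samples[keep, , , drop = FALSE], c(2, 1, 3)) *
      as.vector(density_weights(rs$t, rs$dk)),
    coils = raw$coils, n = n, r = resp_values[keep],
    roi = roi %||% default_heart_roi(n)
  )
}

# Gradient entropy of the pooled density-compensated reconstruction of the
# data corrected with coefficients `cvec`.
fnav_objective <- function(ctx, cvec) {
  proj <- drop(ctx$dirs %*% cvec) * ctx$r
  phase <- exp(2i * pi * outer(ctx$rs$t, proj))
  ncoil <- dim(ctx$coils)[3]
  img <- 0
  for (c in seq_len(ncoil)) {
    a <- radial_nudft_adjoint(coil_slice(ctx$y, c) * phase, ctx$coords,
                              ctx$dirs, ctx$rs$dk, ctx$rs$ns)
    img <- img + Conj(as.vector(ctx$coils[, , c])) * a
  }
  gradient_entropy(matrix(Mod(img), ctx$n, ctx$n), ctx$roi)
}

#' Fit fNAV displacement coefficients
#'
#' Focused navigation: finds the per-axis millimeter coefficients that,
#' multiplied by the unitless respiratory curve and applied as a k-space
#' phase correction, minimize the gradient-image entropy of a pooled
#' density-compensated reconstruction of the bright-blood (FISS) data over a
#' heart region of interest. Derivative-free search: a joint coarse grid
#' over the in-plane axes (the entropy surface couples the axes, so purely
#' sequential scans can be trapped by a joint local minimum), followed by
#' per-axis golden-section refinement to 0.1 mm over two sweeps.
#'
#' @param raw_fiss FISS `raw_acquisition` (motion-corrupted).
#' @param resp_values unitless respiratory curve at the FISS readout
#'   timestamps.
#' @param roi heart ROI (list of `y`, `z` index vectors); defaults to the
#'   central half-FOV box.
#' @param bound_mm per-axis search bound (mm).
#' @param coarse_step_mm coarse grid step (mm).
#' @param tol_mm golden-section tolerance (mm).
#' @param sweeps coordinate-descent sweeps.
#' @param axes integer axes to search (default: in-plane axes for 2d mode,
#'   all three for 3d; unsearched axes stay 0).
#' @param stride readout subsampling stride of the inner pooled
#'   reconstruction used by the objective.
#' @return a [motion_model()] with the achieved entropy and the accepted
#'   objective trace.
#' @export
fit_fnav_coefficients <- function(raw_fiss, resp_values, roi = NULL,
                                  bound_mm = 25, coarse_step_mm = 2,
                                  tol_mm = 0.1, sweeps = 2L, axes = NULL,
                                  stride = 4L) {
  stopifnot(inherits(raw_fiss, "raw_acquisition"))
  sched_t <- raw_fiss$schedule$t
  if (length(resp_values) != length(sched_t)) {
    stopf("resp_values must be sampled at the %d readout timestamps",
          length(sched_t))
  }
  if (all(resp_values == 0)) {
    warnf("degenerate respiratory curve (all zero): returning c = 0")
    return(motion_model(c(0, 0, 0), resp_values, sched_t, entropy = NA))
  }
  axes <- axes %||% if (raw_fiss$grid$mode == "2d") 2:3 else 1:3
  ctx <- fnav_context(raw_fiss, resp_values, roi, stride = stride)

  cvec <- c(0, 0, 0)
  best <- fnav_objective(ctx, cvec)
  trace <- best
  coarse <- seq(-bound_mm, bound_mm, by = 2 * coarse_step_mm)
  if (length(axes) == 2) {
    # joint coarse grid over both searched axes
    for (v1 in coarse) {
      for (v2 in coarse) {
        cc <- cvec; cc[axes[1]] <- v1; cc[axes[2]] <- v2
        val <- fnav_objective(ctx, cc)
        if (val < best) {
          cvec <- cc; best <- val; trace <- c(trace, best)
        }
      }
    }
  } else {
    for (ax in axes) {
      for (v in coarse) {
        cc <- cvec; cc[ax] <- v
        val <- fnav_objective(ctx, cc)
        if (val < best) {
          cvec <- cc; best <- val; trace <- c(trace, best)
        }
      }
    }
  }
  for (sweep in seq_len(sweeps)) {
    for (ax in axes) {
      obj_ax <- function(v) {
        cc <- cvec; cc[ax] <- v
        fnav_objective(ctx, cc)
      }
      lo <- max(cvec[ax] - 2 * coarse_step_mm, -bound_mm)
      hi <- min(cvec[ax] + 2 * coarse_step_mm, bound_mm)
      opt <- optimize(obj_ax, interval = c(lo, hi), tol = tol_mm)
      if (opt$objective < best) {
        cvec[ax] <- opt$minimum; best <- opt$objective
        trace <- c(trace, best)
      }
    }
  }
  motion_model(cvec, resp_values, sched_t, entropy = best, trace = trace)
}
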