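#' Measurement plane specification
#'
#' Axis-aligned or oblique plane through a phase-resolved volume. In 2D
#' (single-slice) mode the slice itself is the measurement plane and the
#' through-plane direction is x; the normal sign fixes the positive flow
#' direction (chosen per vessel so physiologic systolic flow is positive).
#'
#' @param normal unit 3-vector plane normal.
#' @param label "AAo", "DAo" or "other".
#' @param axis,index axis name and slice index for axis-aligned planes in 3D
#'   volumes.
#' @param point point on the plane (mm) for oblique planes.
#' @return object of class `plane_spec`.
#' @export
plane_spec <- function(normal = c(1, 0, 0), label = c("other", "AAo", "DAo"),
                       axis = "x", index = 1L, point = c(0, 0, 0)) {
  label <- match.arg(label)
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-6) stopf("plane normal must be unit-norm")
  structure(list(normal = as.numeric(normal), label = label, axis = axis,
                 index = as.integer(index), point = as.numeric(point)),
            class = "plane_spec")
}

#' Extract per-phase magnitude and through-plane velocity on a plane
#'
#' @param vol a `flow4d` or `synaps_flow4d` object.
#' @param plane a [plane_spec()]. For single-slice volumes only planes with
#'   a through-plane (x) normal are meaningful.
#' @return list with `magnitude` (y, z, P), `v_through` (y, z, P; cm/s,
#'   positive along the plane normal) and `pixel_mm`.
#' @export
extract_plane <- function(vol, plane) {
  stopifnot(inherits(vol, c("flow4d", "synaps_flow4d")))
  nrm <- plane$normal
  d <- dim(vol$velocity)
  if (length(d) != 4) stopf("expected a (y, z, P, 3) velocity array")
  vth <- nrm[1] * vol$velocity[, , , 1] +
    nrm[2] * vol$velocity[, , , 2] + nrm[3] * vol$velocity[, , , 3]
  list(magnitude = vol$magnitude, v_through = vth, pixel_mm = vol$voxel_mm)
}

# Largest-overlap propagation helpers -------------------------------------

# Connected component (8-connectivity) of `mask` containing `seed` (y, z).
component_at <- function(mask, seed) {
  lab <- EBImage::bwlabel(mask)
  id <- lab[seed[1], seed[2]]
  if (id == 0) return(NULL)
  lab == id
}

# Integer centroid of a logical mask.
mask_centroid <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  pmin(pmax(round(colMeans(w)), 1), dim(mask))
}

#' Dynamic vessel segmentation
#'
#' Threshold-plus-connectivity vessel tracing repeated for every cardiac
#' phase: the blood-pool reference intensity is the median inside the
#' phase-1 seed component, the threshold sits at fraction `tau` of the way
#' from the surrounding background level up to that reference (a
#' full-width-at-half-maximum edge criterion, unbiased for any background
#' intensity), and the retained region is the connected component
#' containing the seed, which is propagated between phases as the previous
#' mask's centroid and re-anchored to the initial seed if the centroid
#' drifts off the component. This emulates semi-automatic dynamic vessel
#' tracing with a deterministic rule.
#'
#' @param mag magnitude array (y, z, P).
#' @param seed_point pixel index (y, z) inside the vessel at phase 1.
#' @param tau threshold position between background and blood-pool
#'   reference (0.5 = half maximum).
#' @return logical array (y, z, P) of per-phase masks.
#' @export
segment_vessel_dynamic <- function(mag, seed_point, tau = 0.5) {
  d <- dim(mag)
  P <- d[3]
  seed <- as.integer(seed_point)
  # bootstrap the reference: provisional component from a 3x3 seed median
  nb <- mag[max(seed[1] - 1, 1):min(seed[1] + 1, d[1]),
            max(seed[2] - 1, 1):min(seed[2] + 1, d[2]), 1]
  prov <- component_at(mag[, , 1] >= tau * median(nb), seed)
  if (is.null(prov)) stopf("seed point is below threshold at phase 0")
  ref <- median(mag[, , 1][prov])
  # local background: median of the expanded bounding box around the seed
  # component, component excluded
  w <- which(prov, arr.ind = TRUE)
  ry <- max(min(w[, 1]) - 4, 1):min(max(w[, 1]) + 4, d[1])
  rz <- max(min(w[, 2]) - 4, 1):min(max(w[, 2]) + 4, d[2])
  box <- mag[ry, rz, 1]
  bg <- median(box[!prov[ry, rz]])
  if (bg >= ref) stopf("blood-pool reference does not exceed the background")
  # the half-maximum contour itself belongs to the vessel; the epsilon keeps
  # exactly-half-covered edge pixels from dropping out by float rounding
  level <- bg + tau * (ref - bg) - 1e-9 * (ref - bg)

  masks <- array(FALSE, d)
  seed0 <- as.integer(seed_point)
  for (p in seq_len(P)) {
    thr <- mag[, , p] >= level
    comp <- component_at(thr, seed)
    if (is.null(comp)) comp <- component_at(thr, seed0)  # re-anchor
    if (is.null(comp) || !any(comp)) {
      stopf("vessel component vanished at cardiac phase %d", p - 1L)
    }
    masks[, , p] <- comp
    seed <- mask_centroid(comp)
  }
  masks
}

#' Flow metrics from per-phase masks and velocities
#'
#' Flow rate per phase `Q_p = sum_{pixels in mask} v * pixel_area`,
#' converted to mL/s (cm/s times mm^2 times 0.01); net volume is the
#' flow-rate curve integrated over the RR interval and peak flow its
#' maximum.
#'
#' @param masks logical array (y, z, P).
#' @param vel through-plane velocity array (y, z, P) in cm/s.
#' @param pixel_mm pixel size (mm).
#' @param rr_s RR interval duration (s).
#' @return list with `area_mm2`, `q_ml_s` (per phase), `net_volume_ml`,
#'   `peak_flow_ml_s`.
#' @export
flow_metrics <- function(masks, vel, pixel_mm, rr_s) {
  if (!identical(dim(masks), dim(vel))) stopf("mask / velocity grid mismatch")
  P <- dim(masks)[3]
  area <- q <- numeric(P)
  for (p in seq_len(P)) {
    m <- masks[, , p]
    area[p] <- sum(m) * pixel_mm^2
    q[p] <- sum(vel[, , p][m]) * pixel_mm^2 * 0.01
  }
  list(area_mm2 = area, q_ml_s = q,
       net_volume_ml = sum(q) * rr_s / P,
       peak_flow_ml_s = max(q))
}

#' Blood-to-myocardium contrast ratio
#'
#' Ratio of mean signal intensity between a blood region of interest and a
#' myocardial region of interest.
#'
#' @param mag magnitude image (matrix).
#' @param roi_blood,roi_myo lists of `y`, `z` index vectors (disjoint,
#'   nonempty).
#' @return scalar ratio.
#' @export
contrast_ratio <- function(mag, roi_blood, roi_myo) {
  if (length(roi_blood$y) == 0 || length(roi_myo$y) == 0) stopf("empty ROI")
  b <- mean(mag[roi_blood$y, roi_blood$z])
  m <- mean(mag[roi_myo$y, roi_myo$z])
  if (m == 0) stopf("myocardial ROI mean is zero: ratio undefined")
  b / m
}

#' Dice similarity coefficient
#'
#' `2 |A & B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' Symmetric, and equal to 1 iff the masks are identical.
#'
#' @param a,b logical arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Agreement statistics between two paired series
#'
#' Pearson correlation, linear regression (A on B), Bland-Altman bias and
#' 95% limits of agreement (bias +/- 1.96 SD of the differences A - B),
#' mean absolute error, and a two-sided Wilcoxon signed-rank test. The
#' Bonferroni correction is applied at the reporting layer through
#' `n_comparisons`.
#'
#' @param a,b numeric vectors of equal length >= 3 (A = evaluated method,
#'   B = reference).
#' @param n_comparisons Bonferroni divisor for the adjusted p-value.
#' @return list of class `agreement_stats`.
#' @export
agreement_stats <- function(a, b, n_comparisons = 1L) {
  if (length(a) != length(b) || length(a) < 3) {
    stopf("need paired series of equal length >= 3")
  }
  d <- a - b
  zero_var <- sd(a) == 0 || sd(b) == 0
  r <- if (zero_var) NA_real_ else cor(a, b)
  if (zero_var) {
    slope <- intercept <- r2 <- NA_real_
  } else {
    fit <- lm(a ~ b)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine
  }
  p <- if (all(d == 0)) 1 else
    suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
  list(pearson_r = r, slope = slope, intercept = intercept, r_squared = r2,
       bias = mean(d), loa = mean(d) + c(-1, 1) * 1.96 * sd(d),
       mean_abs_error = mean(abs(d)),
       wilcoxon_p = p, p_bonferroni = min(1, p * n_comparisons),
       zero_variance = zero_var)
}

#' Align flow curves at peak systole
#'
#' Circularly shifts each curve so its maximum lands on the reference
#' (first) curve's maximum; ties resolve to the earliest index.
#'
#' @param curves list of numeric per-phase flow curves of equal length.
#' @return list with integer `shifts` and the `aligned` curves.
#' @export
align_peak_systole <- function(curves) {
  stopifnot(length(curves) >= 1)
  P <- length(curves[[1]])
  ref_peak <- which.max(curves[[1]])
  shifts <- vapply(curves, function(cv) {
    as.integer((which.max(cv) - ref_peak) %% P)
  }, integer(1))
  aligned <- Map(function(cv, s) {  # left-rotate by s phases
    if (s == 0) cv else c(cv[(s + 1):P], cv[1:s])
  }, curves, shifts)
  list(shifts = shifts, aligned = aligned)
}
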