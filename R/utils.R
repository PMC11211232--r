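#' @useDynLib synaps4d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef cor fft fitted lm median optimize prcomp rnorm
#'   runif sd setNames wilcox.test
NULL

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stage seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483629)
}

# Voxel centre coordinates (mm, iso-centre origin) along one axis.
axis_coords_mm <- function(n, voxel_mm) {
  (seq_len(n) - 1 - n / 2) * voxel_mm
}

# nvox x 3 voxel coordinates for a 2D (y,z) slice or a 3D volume.
# 2D arrays are indexed [y, z]; the through-plane x coordinate is 0.
grid_coords_mm <- function(n, voxel_mm, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  ax <- axis_coords_mm(n, voxel_mm)
  if (mode == "2d") {
    g <- expand.grid(y = ax, z = ax, KEEP.OUT.ATTRS = FALSE)
    cbind(x = 0, y = g$y, z = g$z)
  } else {
    g <- expand.grid(x = ax, y = ax, z = ax, KEEP.OUT.ATTRS = FALSE)
    cbind(x = g$x, y = g$y, z = g$z)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
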