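# Versioned native containers for raw acquisitions and derived artifacts.
RAW_FORMAT_VERSION <- "1.0"

write_artifact <- function(x, path, what) {
  saveRDS(list(format = paste0("synaps4d-", what),
               version = RAW_FORMAT_VERSION, payload = x), path)
  invisible(path)
}

read_artifact <- function(path, what) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$format, paste0("synaps4d-", what))) {
    stopf("%s is not a synaps4d %s container", path, what)
  }
  if (!identical(obj$version, RAW_FORMAT_VERSION)) {
    stopf("container version %s does not match library version %s",
          obj$version %||% "<missing>", RAW_FORMAT_VERSION)
  }
  obj$payload
}

#' Write / read a raw acquisition container
#'
#' Lossless, versioned round trip of the full acquisition: complex samples,
#' schedule, coil maps, pilot-tone record, sequence metadata and (for
#' simulated data) the ground-truth block. Reading a file written by a
#' different format version fails with an error naming both versions.
#'
#' @param raw a `raw_acquisition`.
#' @param path file path.
#' @return `write_raw` the path, invisibly; `read_raw` the
#'   `raw_acquisition`.
#' @export
write_raw <- function(raw, path) {
  stopifnot(inherits(raw, "raw_acquisition"))
  write_artifact(raw, path, "raw")
}

#' @rdname write_raw
#' @export
read_raw <- function(path) read_artifact(path, "raw")

# Pack a (y, z, P) array into a 4D NIfTI with the phase on dim 4.
as_phase_nifti <- function(arr, voxel_mm, phase_s) {
  d <- dim(arr)
  img <- RNifti::asNifti(array(arr, c(d[1], d[2], 1, d[3])))
  RNifti::pixdim(img) <- c(voxel_mm, voxel_mm, voxel_mm, phase_s)
  img
}

#' Export reconstructed volumes as NIfTI
#'
#' Cine volumes produce `<prefix>_mag.nii.gz`; flow volumes additionally
#' produce `<prefix>_vx/_vy/_vz.nii.gz` with velocities stored in cm/s as
#' float32. Voxel size and per-phase duration are recorded in the headers.
#'
#' @param vol a `cine4d`, `flow4d` or `synaps_flow4d` object.
#' @param prefix output path prefix.
#' @return character vector of written paths.
#' @export
export_volumes <- function(vol, prefix) {
  phase_s <- if (is.na(vol$rr_s %||% NA)) 1 else vol$rr_s / vol$n_phases
  paths <- character(0)
  p <- paste0(prefix, "_mag.nii.gz")
  RNifti::writeNifti(as_phase_nifti(vol$magnitude, vol$voxel_mm, phase_s),
                     p, datatype = "float")
  paths <- c(paths, p)
  if (!is.null(vol$velocity)) {
    for (k in 1:3) {
      p <- paste0(prefix, "_v", c("x", "y", "z")[k], ".nii.gz")
      RNifti::writeNifti(as_phase_nifti(vol$velocity[, , , k], vol$voxel_mm,
                                        phase_s), p, datatype = "float")
      paths <- c(paths, p)
    }
  }
  paths
}

# Write per-phase flow curves as CSV.
write_flow_curves <- function(metrics, path) {
  utils::write.csv(data.frame(phase = seq_along(metrics$area_mm2) - 1L,
                              area_mm2 = metrics$area_mm2,
                              q_ml_s = metrics$q_ml_s), path,
                   row.names = FALSE)
  invisible(path)
}

# INFO-level stage log: inputs hash, seed and wall time.
log_stage <- function(stage, input_paths, seed, elapsed) {
  md5 <- if (length(input_paths)) {
    paste(substr(unname(tools::md5sum(input_paths)), 1, 8), collapse = ",")
  } else "-"
  message(sprintf("[INFO] stage=%s inputs_md5=%s seed=%s elapsed=%.1fs",
                  stage, md5, as.character(seed), elapsed))
}
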