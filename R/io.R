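# File interfaces: NIfTI volumes (RNifti), plain-text masks with JSON
# sidecars, JSON truth/measurement records, CSV tables, JSON/YAML configs.

write_nifti_volume <- function(arr, path, voxel_size) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a digital phantom
#'
#' Writes `<prefix>_intensity.nii` and `<prefix>_labels.nii` (RAS
#' orientation, voxel size in the header) plus `<prefix>_truth.json`.
#' `read_phantom()` restores the three pieces (the functional spec is not
#' serialised; geometry lives in the truth record and the volumes).
#'
#' @param phantom a `digital_phantom`.
#' @param prefix path prefix for the three output files.
#' @return `write_phantom()` returns the three paths invisibly;
#'   `read_phantom()` returns a list `intensity`, `labels`, `truth`,
#'   `voxel_size`.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "digital_phantom"))
  p1 <- paste0(prefix, "_intensity.nii")
  p2 <- paste0(prefix, "_labels.nii")
  p3 <- paste0(prefix, "_truth.json")
  write_nifti_volume(phantom$intensity, p1, phantom$voxel_size)
  write_nifti_volume(phantom$labels, p2, phantom$voxel_size)
  jsonlite::write_json(c(phantom$truth, list(voxel_size = phantom$voxel_size)),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  intensity <- as.array(RNifti::readNifti(paste0(prefix, "_intensity.nii")))
  labels <- as.array(RNifti::readNifti(paste0(prefix, "_labels.nii")))
  truth <- jsonlite::read_json(paste0(prefix, "_truth.json"), simplifyVector = TRUE)
  list(intensity = intensity, labels = array(as.integer(labels), dim(labels)),
       truth = truth, voxel_size = truth$voxel_size)
}

#' Write / read a sampling mask
#'
#' The mask grid is stored as a plain-text 0/1 matrix; the generation
#' parameters go to a JSON sidecar so the object round-trips.
#'
#' @param mask a `sampling_mask`.
#' @param path output path for the text matrix; the sidecar gets
#'   `<path>.json`.
#' @return `write_mask()` returns the paths invisibly; `read_mask()` a
#'   `sampling_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  write.table(mask$grid * 1L, path, row.names = FALSE, col.names = FALSE)
  meta <- mask[c("ny", "nz", "target_accel", "achieved_fraction",
                 "calib_fraction", "density_decay", "r0", "tol", "seed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(path, paste0(path, ".json")))
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  grid <- as.matrix(read.table(path)) == 1
  dimnames(grid) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rho <- ellipse_rho(meta$ny, meta$nz)
  in_ellipse <- if (isTRUE(all.equal(meta$target_accel, 1)) && all(grid)) {
    matrix(TRUE, meta$ny, meta$nz)
  } else {
    rho <= 1
  }
  m <- new_sampling_mask(grid, rho <= sqrt(meta$calib_fraction), in_ellipse,
                         meta$target_accel, meta$calib_fraction,
                         meta$density_decay, meta$r0 %||% NA_real_,
                         meta$tol, meta$seed %||% NA_integer_)
  m
}

#' Write a measurement record as JSON
#'
#' @param measures an `aneurysm_measures` list.
#' @param path output path.
#' @export
write_measures <- function(measures, path) {
  jsonlite::write_json(unclass(measures), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write an experiment configuration
#'
#' Configurations serialise to JSON or YAML by file extension; key names
#' mirror the [experiment_config()] fields.
#'
#' @param config an `experiment_config`.
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$recon <- unclass(x$recon)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  recon_args <- x$recon %||% list()
  x$recon <- NULL
  do.call(experiment_config, c(x, list(recon = do.call(recon_config, recon_args))))
}
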