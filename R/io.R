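#' Write a scan or density volume as NIfTI
#'
#' Voxel spacing is carried in the NIfTI pixdim; truth masks can be
#' written alongside as 8-bit label images.
#'
#' @param x `ovtr_scan`, `ovtr_density`, or numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing (mm), required for bare arrays.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "ovtr_scan")) { spacing <- x$spacing; x <- x$hu }
  else if (inherits(x, "ovtr_density")) { spacing <- x$spacing; x <- x$density }
  if (is.null(spacing)) stop("spacing required for a bare array")
  if (is.logical(x)) x <- array(as.integer(x), dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep(spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a density image
#' @param path NIfTI file.
#' @return `ovtr_density` with spacing from the header.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1]
  density_image(array(as.numeric(img), dim(img)), sp)
}

#' Write a torque-rotation trace as CSV
#'
#' Two columns with the header `rotation_deg,torque_Nm`.
#' @param trace `ovtr_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(rotation_deg = trace$rotation,
                              torque_Nm = trace$torque),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a torque-rotation trace from CSV
#' @param path CSV with columns `rotation_deg`, `torque_Nm`.
#' @param sampling_rate Sampling rate metadata (Hz).
#' @return `ovtr_trace`.
#' @export
read_trace <- function(path, sampling_rate = 20) {
  df <- utils::read.csv(path)
  stopifnot(all(c("rotation_deg", "torque_Nm") %in% names(df)))
  structure(list(rotation = df$rotation_deg, torque = df$torque_Nm,
                 sampling_rate = sampling_rate),
            class = "ovtr_trace")
}

#' Serialize a calibration to JSON
#' @param calibration `ovtr_calibration`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibration from JSON
#' @param path JSON file written by [write_calibration()].
#' @return `ovtr_calibration`.
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("slope", "intercept", "r_squared", "n_rods")],
            class = "ovtr_calibration")
}
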