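#' Fit a HU-to-density calibration line from a phantom scan
#'
#' Ordinary least-squares fit of mean rod Hounsfield units against the
#' known rod hydroxyapatite densities. The fit is unweighted and invariant
#' to rod ordering.
#'
#' @param phantom Either an `ovtr_scan` from [make_phantom_scan()] (whose
#'   `truth$rod_label` identifies the rods) or a numeric HU array.
#' @param rod_densities Known rod densities (mg HA/cm^3); defaults to the
#'   densities recorded in the phantom's truth for synthetic scans.
#' @param rod_masks For a raw HU array: list of logical masks, one per rod.
#' @return `ovtr_calibration`: list with `slope` (HU per mg HA/cm^3),
#'   `intercept` (HU), `r_squared`, `n_rods`.
#' @export
fit_calibration <- function(phantom, rod_densities = NULL, rod_masks = NULL) {
  if (inherits(phantom, "ovtr_scan")) {
    hu <- phantom$hu
    label <- phantom$truth$rod_label
    if (is.null(label)) stop("scan carries no rod labels")
    rod_densities <- rod_densities %||% phantom$truth$rod_densities
    nr <- length(rod_densities)
    rod_means <- vapply(seq_len(nr), function(i) {
      sel <- label == i
      if (!any(sel))
        stop_ovtr(sprintf("rod %d has an empty mask", i), "ovtr_invalid_input")
      mean(hu[sel])
    }, numeric(1))
  } else {
    if (is.null(rod_masks) || is.null(rod_densities))
      stop("raw HU input requires rod_masks and rod_densities")
    if (length(rod_masks) != length(rod_densities))
      stop("one mask per rod density required")
    rod_means <- vapply(seq_along(rod_masks), function(i) {
      if (!any(rod_masks[[i]]))
        stop_ovtr(sprintf("rod %d has an empty mask", i), "ovtr_invalid_input")
      mean(phantom[rod_masks[[i]]])
    }, numeric(1))
  }
  if (length(rod_densities) < 2)
    stop_ovtr("need at least 2 rods", "ovtr_invalid_input")
  if (length(unique(rod_densities)) < 2)
    stop_ovtr("identical rod densities: singular fit", "ovtr_singular_fit")
  fit <- stats::lm(rod_means ~ rod_densities)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((rod_means - mean(rod_means))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n_rods = length(rod_densities)),
    class = "ovtr_calibration"
  )
}

#' Convert a HU volume to mineral density
#'
#' Inverts the linear calibration voxelwise: density = (HU - intercept) /
#' slope. Negative densities are retained (not clipped) so that noise
#' statistics survive for downstream averaging; thresholds are applied by
#' the segmentation stage instead.
#'
#' @param hu An `ovtr_scan` or a numeric HU array.
#' @param calibration `ovtr_calibration` (or list with slope/intercept).
#' @param spacing Voxel spacing (mm); taken from the scan when available.
#' @return `ovtr_density`: list with `density` (mg HA/cm^3 array),
#'   `spacing`, `provenance`.
#' @export
apply_calibration <- function(hu, calibration, spacing = NULL) {
  if (inherits(hu, "ovtr_scan")) {
    spacing <- spacing %||% hu$spacing
    hu <- hu$hu
  }
  if (is.null(spacing)) stop("spacing required for raw HU input")
  if (abs(calibration$slope) < .Machine$double.eps)
    stop("calibration slope must be non-zero")
  n_bad <- sum(!is.finite(hu))
  if (n_bad > 0)
    stop_ovtr(sprintf("%d non-finite HU voxels in input", n_bad),
              "ovtr_invalid_input")
  structure(
    list(density = (hu - calibration$intercept) / calibration$slope,
         spacing = spacing,
         provenance = list(slope = calibration$slope,
                           intercept = calibration$intercept)),
    class = "ovtr_density"
  )
}

#' Wrap an existing density array as a density image
#' @param density 3-D numeric array (mg HA/cm^3).
#' @param spacing Voxel spacing (mm).
#' @return `ovtr_density` object.
#' @export
density_image <- function(density, spacing) {
  stopifnot(is.numeric(density), is_scalar_num(spacing), spacing > 0)
  structure(list(density = density, spacing = spacing,
                 provenance = list()),
            class = "ovtr_density")
}
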