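#' Segment new callus from a calibrated density image
#'
#' Transparent replacement for proprietary callus-separation workflows:
#' the pre-existing cortical bone is supplied as a mask (from day-0
#' geometry; in synthetic studies, the generator's truth mask), and new
#' mineralised callus is everything at or above the mineralisation
#' threshold, inside the analysis slab, outside old bone, after removal of
#' small disconnected islands.
#'
#' @param density `ovtr_density` image (mg HA/cm^3).
#' @param old_bone_mask Logical array on the same grid marking pre-existing
#'   cortical bone.
#' @param roi Axial slab `c(z_min, z_max)` in mm (half-open, z = 0 at the
#'   volume centre), or `NULL` for the full volume.
#' @param mineralization_threshold Voxel inclusion cutoff (mg HA/cm^3);
#'   default 450.
#' @param min_component Minimum connected-component size (voxels) retained
#'   after thresholding; default 50.
#' @return `ovtr_segmentation`: logical `callus_mask` and `old_bone_mask`,
#'   plus the roi and threshold used.
#' @export
segment_callus <- function(density, old_bone_mask, roi = NULL,
                           mineralization_threshold = 450,
                           min_component = 50) {
  stopifnot(inherits(density, "ovtr_density"))
  d <- dim(density$density)
  if (!identical(dim(old_bone_mask), d))
    stop_ovtr("old_bone_mask grid does not match density grid",
              "ovtr_grid_mismatch")
  nz <- d[3]
  zs <- (seq_len(nz) - (nz + 1) / 2) * density$spacing
  if (is.null(roi)) {
    in_roi_z <- rep(TRUE, nz)
  } else {
    stopifnot(length(roi) == 2)
    in_roi_z <- zs >= roi[1] & zs < roi[2]
    if (!any(in_roi_z))
      stop_ovtr("roi slab contains no slices", "ovtr_invalid_input")
  }
  mask <- density$density >= mineralization_threshold & !old_bone_mask
  mask[, , !in_roi_z] <- FALSE
  if (any(mask) && min_component > 1) {
    lab <- cc_label_3d(as.vector(mask), d)
    keep <- which(tabulate(lab[lab > 0L]) >= min_component)
    mask <- array(lab %in% keep, d)
  }
  structure(
    list(callus_mask = mask, old_bone_mask = old_bone_mask, roi = roi,
         mineralization_threshold = mineralization_threshold,
         spacing = density$spacing),
    class = "ovtr_segmentation"
  )
}

#' Callus volume and mean mineral density
#'
#' Volume is voxel count times voxel volume (converted mm^3 to cm^3);
#' density is the mean calibrated density over the callus mask. An empty
#' mask yields volume 0 and density `NA` (undefined, not 0).
#'
#' @param seg `ovtr_segmentation` from [segment_callus()], or a logical
#'   mask array.
#' @param density `ovtr_density` image on the same grid.
#' @return List with `callus_volume` (cm^3), `callus_density`
#'   (mg HA/cm^3), `voxel_count`.
#' @export
compute_morphometry <- function(seg, density) {
  stopifnot(inherits(density, "ovtr_density"))
  mask <- if (inherits(seg, "ovtr_segmentation")) seg$callus_mask else seg
  if (!identical(dim(mask), dim(density$density)))
    stop_ovtr("mask grid does not match density grid", "ovtr_grid_mismatch")
  n <- sum(mask)
  vol <- n * density$spacing^3 / 1000
  dens <- if (n > 0) mean(density$density[mask]) else NA_real_
  list(callus_volume = vol, callus_density = dens, voxel_count = n)
}

#' Dice overlap coefficient between two masks
#' @param a,b Logical arrays of identical dimension.
#' @return Dice coefficient in `[0, 1]` (1 when both masks are empty).
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
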