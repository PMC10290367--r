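#' Scan geometry for a synthetic osteotomized tibia
#'
#' Describes the idealised diaphysis used by [make_tibia_scan()]: a hollow
#' cylinder (cortex) of given outer radius and cortical thickness,
#' interrupted by a transverse osteotomy gap centred on the bone axis.
#'
#' @param outer_radius Outer cortex radius (mm).
#' @param cortical_thickness Cortical wall thickness (mm); the endosteal
#'   (medullary) radius is `outer_radius - cortical_thickness`.
#' @param bone_length Axial field-of-view length (mm).
#' @param gap_width Transverse osteotomy gap (mm); 3 and 17 are the typical
#'   non-critical and critical defect sizes. 0 gives an intact bone.
#' @param voxel_spacing Isotropic voxel spacing (mm). The default 0.2 mm is
#'   deliberately coarser than a clinical micro-CT scanner so that full
#'   pipelines run at desk scale; all downstream results are computed
#'   per-spacing.
#' @param field_halfwidth Transverse half-width of the reconstructed field
#'   of view (mm); must leave room for the periosteal callus envelope. The
#'   default `2.5 * outer_radius` accommodates calluses of roughly twice
#'   the largest group-mean volume before the capacity check trips.
#' @return An object of class `ovtr_geometry`.
#' @export
scan_geometry <- function(outer_radius = 10, cortical_thickness = 4,
                          bone_length = 80, gap_width = 17,
                          voxel_spacing = 0.2,
                          field_halfwidth = 2.5 * outer_radius) {
  stopifnot(
    is_scalar_num(outer_radius), is_scalar_num(cortical_thickness),
    is_scalar_num(bone_length), is_scalar_num(gap_width),
    is_scalar_num(voxel_spacing), is_scalar_num(field_halfwidth)
  )
  if (!(outer_radius > cortical_thickness && cortical_thickness > 0))
    stop("need outer_radius > cortical_thickness > 0")
  if (!(gap_width >= 0 && gap_width < bone_length))
    stop("need 0 <= gap_width < bone_length")
  if (voxel_spacing <= 0) stop("voxel_spacing must be > 0")
  if (field_halfwidth <= outer_radius)
    stop("field_halfwidth must exceed outer_radius")
  structure(
    list(outer_radius = outer_radius,
         cortical_thickness = cortical_thickness,
         inner_radius = outer_radius - cortical_thickness,
         bone_length = bone_length, gap_width = gap_width,
         voxel_spacing = voxel_spacing, field_halfwidth = field_halfwidth),
    class = "ovtr_geometry"
  )
}

#' Callus specification for the synthetic generator
#'
#' Set-points for the mineralising callus rendered by [make_tibia_scan()]:
#' total mineralised volume, mean mineral density, and the split between
#' the periosteal sleeve (outside the original cortex envelope) and the
#' endosteal/gap components.
#'
#' @param target_volume Total callus volume (cm^3).
#' @param target_mean_density Mean callus mineral density (mg HA/cm^3).
#' @param periosteal_fraction Share of callus volume lying outside the
#'   original cortex envelope, in `[0, 1]`.
#' @param density_noise_sd Voxel-level SD of callus mineral density
#'   (mg HA/cm^3) around the target mean; models tissue heterogeneity.
#' @return An object of class `ovtr_callus_spec`.
#' @export
callus_spec <- function(target_volume, target_mean_density,
                        periosteal_fraction = 0.7, density_noise_sd = 30) {
  stopifnot(is_scalar_num(target_volume), is_scalar_num(target_mean_density),
            is_scalar_num(periosteal_fraction), is_scalar_num(density_noise_sd))
  if (target_volume < 0) stop("target_volume must be >= 0")
  if (target_volume > 0 &&
      !(target_mean_density > 0 && target_mean_density < 1500))
    stop("target_mean_density must be in (0, 1500) mg HA/cm^3")
  if (periosteal_fraction < 0 || periosteal_fraction > 1)
    stop("periosteal_fraction must be in [0, 1]")
  if (density_noise_sd < 0) stop("density_noise_sd must be >= 0")
  structure(
    list(target_volume = target_volume,
         target_mean_density = target_mean_density,
         periosteal_fraction = periosteal_fraction,
         density_noise_sd = density_noise_sd),
    class = "ovtr_callus_spec"
  )
}

new_scan <- function(hu, spacing, truth, geometry = NULL) {
  structure(list(hu = hu, spacing = spacing, truth = truth,
                 geometry = geometry),
            class = "ovtr_scan")
}

#' @export
print.ovtr_scan <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<ovtr_scan> %d x %d x %d voxels @ %.3g mm\n",
              d[1], d[2], d[3], x$spacing))
  invisible(x)
}

#' Synthetic density-phantom scan
#'
#' Renders a calibration phantom: one homogeneous cylindrical rod per known
#' hydroxyapatite density, mapped to Hounsfield units through a linear
#' HU = slope * density + intercept model with optional additive Gaussian
#' noise. The returned truth carries per-rod label masks and the true
#' calibration line, so [fit_calibration()] can be validated exactly.
#'
#' @param rod_densities Known rod densities (mg HA/cm^3); at least two
#'   distinct values are required for a calibration to be determined.
#' @param calibration Numeric `c(slope, intercept)` of the true HU line.
#' @param noise_sd Additive HU noise SD.
#' @param spacing Isotropic voxel spacing (mm).
#' @param rod_radius,rod_length Rod dimensions (mm).
#' @param seed Optional RNG seed; the generator is a pure function of its
#'   arguments and seed.
#' @return `ovtr_scan` whose `truth$rod_label` labels rod i with integer i.
#' @export
make_phantom_scan <- function(rod_densities, calibration = c(1, 0),
                              noise_sd = 0, spacing = 0.2,
                              rod_radius = 2, rod_length = 4, seed = NULL) {
  if (length(rod_densities) < 2 || length(unique(rod_densities)) < 2)
    stop_ovtr("need at least 2 distinct rod densities (calibration underdetermined)",
              "ovtr_invalid_input")
  stopifnot(length(calibration) == 2, all(is.finite(calibration)))
  nr <- length(rod_densities)
  # rods laid out along x, separated by one rod diameter
  pitch <- 4 * rod_radius
  nx <- ceiling((nr * pitch) / spacing)
  ny <- ceiling((4 * rod_radius) / spacing)
  nz <- ceiling(rod_length / spacing)
  xs <- (seq_len(nx) - 0.5) * spacing
  ys <- (seq_len(ny) - 0.5) * spacing - (ny * spacing) / 2
  label <- array(0L, c(nx, ny, nz))
  rho <- array(0, c(nx, ny, nz))
  for (i in seq_len(nr)) {
    cx <- (i - 0.5) * pitch
    in_rod <- outer((xs - cx)^2, ys^2, `+`) <= rod_radius^2
    sel <- which(in_rod)
    for (k in seq_len(nz)) {
      idx <- sel + (k - 1L) * nx * ny
      label[idx] <- i
      rho[idx] <- rod_densities[i]
    }
  }
  hu <- calibration[1] * rho + calibration[2]
  if (noise_sd > 0)
    hu <- hu + with_seed(seed, array(stats::rnorm(length(hu), 0, noise_sd),
                                     dim(hu)))
  new_scan(hu, spacing,
           truth = list(rod_label = label, rod_densities = rod_densities,
                        calibration = c(slope = calibration[1],
                                        intercept = calibration[2])))
}

# Count of transverse grid voxels with squared radius <= r2 (precomputed
# sorted squared radii make callus volume targeting O(log n) per slice).
count_within <- function(r2sorted, r2) findInterval(r2 + 1e-12, r2sorted)

#' Synthetic osteotomized tibia micro-CT scan
#'
#' Renders a hollow-cylinder diaphysis interrupted by a transverse gap,
#' with a mineralising callus composed of a fusiform periosteal sleeve
#' (outer envelope `R(z) = r_o + A cos^2(pi z / Lc)`), a fill of the
#' resected cortex cross-section across the gap, and an endosteal plug.
#' The sleeve amplitude `A` and plug length are solved on the voxel grid so
#' that the ground-truth callus volume matches `callus$target_volume`
#' within discretisation error. Mineral density is mapped to HU through the
#' given linear calibration with optional additive Gaussian noise.
#'
#' @param geometry [scan_geometry()] object.
#' @param callus [callus_spec()] object; `target_volume = 0` renders no
#'   callus.
#' @param cortical_density Old-cortex mineral density (mg HA/cm^3).
#' @param calibration Numeric `c(slope, intercept)` of the true HU line.
#' @param noise_sd Additive HU noise SD.
#' @param callus_length Axial extent of the callus region (mm); defaults to
#'   `gap_width + 20`, the defect-centred analysis slab.
#' @param seed Optional RNG seed (pure-function contract).
#' @return `ovtr_scan` with truth masks `old_bone`, `callus`, `body`
#'   (bone + callus + medullary canal) and the true calibration.
#' @export
make_tibia_scan <- function(geometry, callus,
                            cortical_density = 1200, calibration = c(1, 0),
                            noise_sd = 0,
                            callus_length = min(geometry$gap_width + 20,
                                                geometry$bone_length - 2),
                            seed = NULL) {
  stopifnot(inherits(geometry, "ovtr_geometry"),
            inherits(callus, "ovtr_callus_spec"))
  sp <- geometry$voxel_spacing
  r_o <- geometry$outer_radius
  r_i <- geometry$inner_radius
  gap <- geometry$gap_width
  half <- geometry$field_halfwidth
  nx <- ny <- 2L * as.integer(ceiling(half / sp))
  nz <- as.integer(round(geometry$bone_length / sp))
  vox_mm3 <- sp^3

  xs <- (seq_len(nx) - (nx + 1) / 2) * sp
  r2 <- outer(xs^2, xs^2, `+`)          # transverse squared radii
  r2sorted <- sort(as.vector(r2))
  zs <- (seq_len(nz) - (nz + 1) / 2) * sp  # z = 0 at gap centre

  in_gap <- abs(zs) < gap / 2
  in_callus_z <- abs(zs) <= callus_length / 2

  # Callus model: a fusiform envelope F(z) = base(z) + A cos^2(pi z / Lc)
  # grows from the resected endosteal radius inside the gap (base r_i) and
  # from the periosteal surface outside it (base r_o), plus an endosteal
  # plug of radius r_i whose length takes the endosteal volume share. Small
  # calluses therefore fill the gap only partially instead of hitting a
  # geometric volume floor.
  target_vox <- callus$target_volume * 1000 / vox_mm3
  A <- 0; plug_half <- 0
  plug_r2 <- numeric(nz)          # per-slice squared plug radius
  base_r <- ifelse(in_gap, r_i, r_o)
  n_plug_slice <- count_within(r2sorted, r_i^2)
  if (callus$target_volume > 0) {
    n_endo_target <- (1 - callus$periosteal_fraction) * target_vox
    plug_slices <- if (n_plug_slice > 0) n_endo_target / n_plug_slice else 0
    plug_half <- min(max(gap / 2, plug_slices * sp / 2), callus_length / 2)
    in_plug_z <- abs(zs) <= plug_half
    n_plug <- n_plug_slice * sum(in_plug_z)
    total_count <- function(A) {
      Fz2 <- (base_r + A * cos(pi * zs / (callus_length + 1e-9))^2)^2
      n <- n_plug
      for (k in which(in_callus_z)) {
        n <- n + count_within(r2sorted, Fz2[k]) -
          count_within(r2sorted, base_r[k]^2)
      }
      n
    }
    if (n_plug >= target_vox) {
      # even the bare plug overshoots: shrink it, filling whole slices
      # from the gap centre outwards plus one partial-radius end disc for
      # sub-slice volume accuracy (the gap may then be unbridged, the
      # faithful image of an insufficient callus)
      ord <- order(abs(zs))
      n_full <- floor(target_vox / n_plug_slice)
      rem <- round(target_vox - n_full * n_plug_slice)
      if (n_full > 0) plug_r2[ord[seq_len(n_full)]] <- r_i^2
      if (rem > 0) plug_r2[ord[n_full + 1]] <- r2sorted[rem]
      plug_half <- max(abs(zs[plug_r2 > 0]), 0)
    } else {
      A_max <- half - r_o - sp
      if (total_count(A_max) < target_vox)
        stop_ovtr(sprintf(
          "callus target volume %.3g cm^3 unachievable within field of view",
          callus$target_volume), "ovtr_capacity_error")
      lo <- 0; hi <- A_max
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (total_count(mid) < target_vox) lo <- mid else hi <- mid
      }
      A <- hi
      plug_r2[in_plug_z] <- r_i^2
    }
  }

  old_bone <- array(FALSE, c(nx, ny, nz))
  cal_mask <- array(FALSE, c(nx, ny, nz))
  body <- array(FALSE, c(nx, ny, nz))
  rho <- array(0, c(nx, ny, nz))

  cortex_slice <- r2 <= r_o^2 & r2 > r_i^2
  canal_slice <- r2 <= r_i^2
  Fz <- base_r + A * cos(pi * zs / (callus_length + 1e-9))^2
  for (k in seq_len(nz)) {
    ob <- if (in_gap[k]) matrix(FALSE, nx, ny) else cortex_slice
    cb <- matrix(FALSE, nx, ny)
    if (callus$target_volume > 0 && in_callus_z[k] && A > 0) {
      # fusiform envelope above the slice's base radius (sleeve outside
      # the gap, partial-to-full gap fill inside it)
      cb <- r2 <= Fz[k]^2 & r2 > base_r[k]^2
    }
    if (plug_r2[k] > 0) cb <- cb | (r2 <= plug_r2[k])  # endosteal plug
    cb <- cb & !ob
    old_bone[, , k] <- ob
    cal_mask[, , k] <- cb
    # the medullary canal counts as body only where bone or callus encloses
    # it; in an unbridged gap the soft tissue is not part of the load path
    body[, , k] <- ob | cb | (if (in_gap[k]) matrix(FALSE, nx, ny)
                              else canal_slice)
  }
  rho[old_bone] <- cortical_density
  rho[cal_mask] <- callus$target_mean_density

  n_cal <- sum(cal_mask)
  out <- with_seed(seed, {
    if (callus$density_noise_sd > 0 && n_cal > 0)
      rho[cal_mask] <- rho[cal_mask] +
        stats::rnorm(n_cal, 0, callus$density_noise_sd)
    hu <- calibration[1] * rho + calibration[2]
    if (noise_sd > 0)
      hu <- hu + array(stats::rnorm(length(hu), 0, noise_sd), dim(hu))
    hu
  })

  new_scan(out, sp,
           truth = list(old_bone = old_bone, callus = cal_mask, body = body,
                        density = rho,
                        calibration = c(slope = calibration[1],
                                        intercept = calibration[2]),
                        callus_volume_cm3 = n_cal * vox_mm3 / 1000),
           geometry = geometry)
}
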