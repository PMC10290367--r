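#' Analytic torsional-rigidity surrogate for summary-level studies
#'
#' Closed-form stand-in for the image-based virtual torsion test, used
#' when study replicates are simulated at summary level (image stages
#' bypassed). The operated diaphysis is modelled as the same idealised
#' geometry the scan generator renders — cortex interrupted by the gap,
#' fusiform periosteal sleeve, gap fill and endosteal plug — and its
#' torsional rigidity is the series combination of per-slice Saint-Venant
#' rigidities, with the shear modulus taken from the dual-zone material
#' law at the callus mean density. The surrogate is monotone in callus
#' volume and density by construction; it is directional, not calibrated
#' to absolute scanner-derived values.
#'
#' @param callus_volume Callus volume (cm^3).
#' @param callus_density Mean callus mineral density (mg HA/cm^3).
#' @param geometry [scan_geometry()] object (spacing is ignored).
#' @param material [material_model()].
#' @param cortical_density Old-cortex density (mg HA/cm^3).
#' @param periosteal_fraction Periosteal share of callus volume.
#' @param n_slices Axial integration resolution.
#' @return Virtual torsional rigidity (Nm^2/deg).
#' @export
vtr_surrogate <- function(callus_volume, callus_density,
                          geometry = scan_geometry(),
                          material = material_model(),
                          cortical_density = 1200,
                          periosteal_fraction = 0.7, n_slices = 400) {
  r_o <- geometry$outer_radius
  r_i <- geometry$inner_radius
  gap <- geometry$gap_width
  Lc <- min(gap + 20, geometry$bone_length - 2)
  L <- geometry$bone_length
  G <- function(E) E / (2 * (1 + material$poisson))
  G_cortex <- G(assign_modulus(cortical_density, material))
  G_callus <- G(assign_modulus(callus_density, material))

  # same shape family as the voxel generator: fusiform envelope
  # F(z) = base(z) + A cos^2(pi z / Lc), base r_i inside the gap and r_o
  # outside, plus an endosteal plug carrying the endosteal volume share
  vol_mm3 <- callus_volume * 1000
  v_endo <- (1 - periosteal_fraction) * vol_mm3
  plug_half <- min(max(gap / 2, v_endo / (pi * r_i^2) / 2), Lc / 2)
  v_plug <- pi * r_i^2 * 2 * plug_half
  z_c <- seq(-Lc / 2, Lc / 2, length.out = n_slices)
  base_c <- ifelse(abs(z_c) < gap / 2, r_i, r_o)
  A <- 0
  if (v_plug >= vol_mm3) {
    plug_half <- vol_mm3 / (pi * r_i^2) / 2      # unbridged small callus
  } else {
    env_vol <- function(A) {
      F <- base_c + A * cos(pi * z_c / Lc)^2
      sum(pi * (F^2 - base_c^2)) * (Lc / n_slices)
    }
    lo <- 0; hi <- 10 * r_o
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (v_plug + env_vol(mid) < vol_mm3) lo <- mid else hi <- mid
    }
    A <- hi
  }

  z <- seq(-L / 2, L / 2, length.out = n_slices)
  dz <- L / (n_slices - 1)
  in_cal <- abs(z) <= Lc / 2
  base_z <- ifelse(abs(z) < gap / 2, r_i, r_o)
  Fz <- ifelse(in_cal, base_z + A * cos(pi * z / Lc)^2, base_z)
  in_gap <- abs(z) < gap / 2
  in_plug <- abs(z) <= plug_half
  J_ann <- function(ro, ri) pi * (ro^4 - ri^4) / 2
  GJ <- numeric(n_slices)
  for (k in seq_len(n_slices)) {
    if (in_gap[k]) {
      # no cortex: callus disc (gap fill above the plug radius, plug core)
      r_disc <- if (in_plug[k]) max(Fz[k], r_i) else
        (if (A > 0) Fz[k] else 0)
      GJ[k] <- G_callus * J_ann(r_disc, 0)
    } else {
      GJ[k] <- G_cortex * J_ann(r_o, r_i) +
        G_callus * J_ann(Fz[k], r_o)             # periosteal sleeve
      if (in_plug[k]) GJ[k] <- GJ[k] + G_callus * J_ann(r_i, 0)
    }
  }
  if (any(GJ <= 0)) return(0)
  k_rad <- 1 / sum(dz / GJ)       # N mm / rad over the whole gauge
  # VTR = (T / theta_deg) * L_m = k_rad * (pi/180) * L * 1e-6
  k_rad * (pi / 180) * L * 1e-6
}

#' Analytic VTR of the intact contralateral diaphysis
#' @inheritParams vtr_surrogate
#' @return Rigidity (Nm^2/deg) of the intact cortical tube.
#' @export
vtr_surrogate_intact <- function(geometry = scan_geometry(),
                                 material = material_model(),
                                 cortical_density = 1200) {
  E <- assign_modulus(cortical_density, material)
  vtr_hollow_cylinder(E, material$poisson, geometry$outer_radius,
                      geometry$inner_radius)
}
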