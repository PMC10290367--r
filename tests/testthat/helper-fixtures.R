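# Fixtures built in code: small geometries and models shared across tests.

# Uniform-modulus hollow-cylinder voxel FE model (the analytic benchmark).
make_cylinder_model <- function(spacing, r_o = 5, r_i = 3, L = 10,
                                E = 10000, nu = 0.3) {
  half <- r_o + 2 * spacing
  nx <- 2L * as.integer(ceiling(half / spacing))
  nz <- as.integer(round(L / spacing))
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing
  r2 <- outer(xs^2, xs^2, `+`)
  ann <- r2 <= r_o^2 & r2 > r_i^2
  keep <- array(rep(ann, nz), c(nx, nx, nz))
  rho <- array(0, dim(keep))
  rho[keep] <- 1200
  # gamma = 0 makes the bone law a constant E for any density
  mat <- material_model(soft_threshold = 0, soft_modulus = 50,
                        E_ref = E, rho_ref = 1200, gamma = 0, poisson = nu)
  build_fe_model(density_image(rho, spacing), mat, keep)
}

# Identity calibration object without fitting a phantom.
identity_calibration <- function() {
  structure(list(slope = 1, intercept = 0, r_squared = 1, n_rods = 2),
            class = "ovtr_calibration")
}

# Small operated-tibia geometry that keeps image tests fast.
small_geometry <- function(gap = 17, spacing = 0.5) {
  scan_geometry(outer_radius = 8, cortical_thickness = 3, bone_length = 50,
                gap_width = gap, voxel_spacing = spacing)
}

# Brute-force two-tailed Mann-Whitney p by direct enumeration of group
# labelings, recomputing U from pair counts (independent of the package's
# rank-sum path).
mw_bruteforce_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
  }
  u_obs <- u_of(a, b)
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
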