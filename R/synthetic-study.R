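#' Synthetic torque-rotation trace from a torsion test
#'
#' Emulates a displacement-controlled torsion rig: internal rotation ramps
#' at `rate` deg/min, sampled at `sampling` Hz, stopping at the first
#' sample that reaches either the torque cap or the rotation cap. The
#' underlying response is bilinear: zero torque over a settling toe region,
#' then linear with the true stiffness, plus additive measurement noise.
#'
#' @param true_stiffness Slope of the linear regime (Nm/deg), > 0.
#' @param rate Rotation rate (deg/min); default 5.
#' @param sampling Sampling rate (Hz); default 20.
#' @param torque_cap,angle_cap Stop conditions; defaults 10 Nm and 12 deg.
#' @param noise_sd Torque measurement noise SD (Nm).
#' @param toe_region Rotation (deg) over which the specimen settles before
#'   the linear regime; motivates the 6-10 Nm regression window.
#' @param seed Optional RNG seed.
#' @return An `ovtr_trace`: list with `rotation` (deg), `torque` (Nm),
#'   `sampling_rate` (Hz).
#' @export
make_torsion_trace <- function(true_stiffness, rate = 5, sampling = 20,
                               torque_cap = 10, angle_cap = 12,
                               noise_sd = 0, toe_region = 0.5, seed = NULL) {
  stopifnot(is_scalar_num(true_stiffness), true_stiffness > 0,
            rate > 0, sampling > 0)
  dtheta <- rate / 60 / sampling
  # the rotation cap bounds the trace: last sample at or just below it
  n <- floor(angle_cap / dtheta + 1e-9) + 1L   # include theta = 0
  if (n > 1e6)
    stop_ovtr("neither torque nor angle cap reachable within 1e6 samples",
              "ovtr_invalid_input")
  rotation <- (seq_len(n) - 1L) * dtheta
  torque <- pmax(0, true_stiffness * (rotation - toe_region))
  if (noise_sd > 0)
    torque <- torque + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  # the machine stops at the first measured sample reaching the torque cap,
  # otherwise runs to the rotation cap
  hit <- which(torque >= torque_cap)[1]
  if (!is.na(hit)) {
    rotation <- rotation[seq_len(hit)]
    torque <- torque[seq_len(hit)]
  }
  structure(list(rotation = rotation, torque = torque,
                 sampling_rate = sampling),
            class = "ovtr_trace")
}

#' Arm set-points matching the 17-mm graft model summaries
#'
#' Group means and SDs (Control vs CEMF) for callus volume (cm^3), callus
#' mineral density (mg HA/cm^3), operated-limb torsional rigidity and
#' contralateral (non-operated) rigidity (Nm^2/deg).
#' @return Named list of per-arm `(mean, sd)` pairs.
#' @export
arm_specs_17mm <- function() {
  list(
    Control = list(callus_volume = c(mean = 7.3, sd = 1.3),
                   callus_density = c(mean = 674, sd = 82),
                   op_rigidity = c(mean = 0.32, sd = 0.31),
                   nonop_rigidity = c(mean = 1.10, sd = 0.20)),
    CEMF = list(callus_volume = c(mean = 12.0, sd = 2.3),
                callus_density = c(mean = 762, sd = 56),
                op_rigidity = c(mean = 0.85, sd = 0.37),
                nonop_rigidity = c(mean = 1.25, sd = 0.21))
  )
}

#' Arm set-points matching the 3-mm gap model summaries
#' @return Named list of per-arm `(mean, sd)` pairs.
#' @export
arm_specs_3mm <- function() {
  list(
    Control = list(callus_volume = c(mean = 11.0, sd = 8.0),
                   callus_density = c(mean = 659, sd = 54),
                   op_rigidity = c(mean = 0.47, sd = 0.39),
                   nonop_rigidity = c(mean = 0.88, sd = 0.23)),
    CEMF = list(callus_volume = c(mean = 10.9, sd = 4.1),
                callus_density = c(mean = 750, sd = 87),
                op_rigidity = c(mean = 0.95, sd = 0.41),
                nonop_rigidity = c(mean = 1.14, sd = 0.29))
  )
}

#' Two-arm study design
#'
#' @param n_per_arm Animals per arm (>= 2).
#' @param arm_specs Per-arm distributions as returned by
#'   [arm_specs_17mm()] / [arm_specs_3mm()].
#' @param seed Integer seed controlling all sampling.
#' @return `ovtr_design` object.
#' @export
study_design <- function(n_per_arm = 6, arm_specs = arm_specs_17mm(),
                         seed = 1) {
  stopifnot(is_scalar_num(n_per_arm), n_per_arm >= 2)
  for (arm in arm_specs) for (q in arm)
    if (q[["sd"]] < 0) stop("all SDs must be >= 0")
  structure(list(n_per_arm = as.integer(n_per_arm), arm_specs = arm_specs,
                 seed = seed),
            class = "ovtr_design")
}

# Truncated-normal draw by redraw: strictly positive quantities are redrawn
# until positive; the number of redraws is recorded.
rtruncpos <- function(n, mean, sd, counter) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    counter$n <- counter$n + length(bad)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

#' Sample per-subject ground truth for a two-arm study
#'
#' Draws each subject's callus volume, callus density, operated-limb
#' rigidity and contralateral rigidity from the arm distributions
#' (independent normals, truncated to positive values by redraw; the
#' number of redraws is reported in the `truncation_redraws` attribute).
#'
#' @param design [study_design()] object.
#' @return data.frame with one row per subject: `subject_id`, `arm`,
#'   `callus_volume`, `callus_density`, `op_rigidity`, `nonop_rigidity`.
#' @export
sample_study <- function(design) {
  stopifnot(inherits(design, "ovtr_design"))
  counter <- new.env(); counter$n <- 0L
  n <- design$n_per_arm
  with_seed(design$seed, {
    rows <- lapply(names(design$arm_specs), function(arm) {
      sp <- design$arm_specs[[arm]]
      data.frame(
        subject_id = paste0(substr(arm, 1, 1), seq_len(n)),
        arm = arm,
        callus_volume = rtruncpos(n, sp$callus_volume[["mean"]],
                                  sp$callus_volume[["sd"]], counter),
        callus_density = rtruncpos(n, sp$callus_density[["mean"]],
                                   sp$callus_density[["sd"]], counter),
        op_rigidity = rtruncpos(n, sp$op_rigidity[["mean"]],
                                sp$op_rigidity[["sd"]], counter),
        nonop_rigidity = rtruncpos(n, sp$nonop_rigidity[["mean"]],
                                   sp$nonop_rigidity[["sd"]], counter),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    attr(out, "truncation_redraws") <- counter$n
    out
  })
}
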