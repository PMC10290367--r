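#' Configuration for an end-to-end synthetic study run
#'
#' Collects every tunable of the pipeline stages: study design, scan
#' generation, calibration, segmentation, virtual torsion, and
#' biomechanics. The configuration round-trips through JSON unchanged and
#' its hash is recorded in the run manifest.
#'
#' @param model `"17mm"` or `"3mm"` osteotomy model; selects the arm
#'   set-points and gap width.
#' @param n_per_arm Animals per arm.
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it.
#' @param spacing Synthetic scan voxel spacing (mm).
#' @param fe_spacing Working resolution of the virtual torsion stage (mm).
#' @param image_stages If `FALSE`, morphometry values are taken from the
#'   sampled ground truth and VTR from the analytic surrogate
#'   (summary-level simulation; the image and FE stages are bypassed).
#' @param gauge_length Biomechanical gauge length (mm).
#' @param window Stiffness regression window (Nm).
#' @param rod_densities Phantom rod densities (mg HA/cm^3).
#' @param calibration True HU line `c(slope, intercept)` of the synthetic
#'   scanner.
#' @param hu_noise_sd Scanner HU noise SD.
#' @param trace_noise_sd Torque measurement noise SD (Nm).
#' @param mineralization_threshold Morphometric segmentation cutoff
#'   (mg HA/cm^3).
#' @param min_component Minimum island size kept by segmentation (voxels).
#' @param toe_region Settling toe of synthetic torsion traces (deg).
#' @param fe_tol Relative residual tolerance of the FE solver.
#' @param material `ovtr_material` model for the FE stage.
#' @param geometry Optional [scan_geometry()]; defaults to the model's gap
#'   width at `spacing`.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return `ovtr_config` list.
#' @export
run_config <- function(model = c("17mm", "3mm"), n_per_arm = 6, seed = 1,
                       spacing = 0.5, fe_spacing = 1.0,
                       image_stages = TRUE, gauge_length = 100,
                       window = c(6, 10),
                       rod_densities = c(0, 100, 200, 400, 800),
                       calibration = c(1.0, 0.0), hu_noise_sd = 20,
                       trace_noise_sd = 0.05,
                       mineralization_threshold = 450,
                       min_component = 50, toe_region = 0.5, fe_tol = 1e-8,
                       material = material_model(), geometry = NULL,
                       out_dir = NULL) {
  model <- match.arg(model)
  gap <- if (model == "17mm") 17 else 3
  geometry <- geometry %||%
    scan_geometry(gap_width = gap, voxel_spacing = spacing)
  structure(
    list(model = model, n_per_arm = n_per_arm, seed = seed,
         spacing = spacing, fe_spacing = fe_spacing,
         image_stages = image_stages, gauge_length = gauge_length,
         window = window, rod_densities = rod_densities,
         calibration = calibration, hu_noise_sd = hu_noise_sd,
         trace_noise_sd = trace_noise_sd,
         mineralization_threshold = mineralization_threshold,
         min_component = min_component, toe_region = toe_region,
         fe_tol = fe_tol,
         material = material, geometry = geometry, out_dir = out_dir),
    class = "ovtr_config"
  )
}

config_hash <- function(config) {
  flat <- config[setdiff(names(config), "out_dir")]
  fnv1a32(paste(deparse(flat), collapse = ""))
}

# Down-sample a logical mask to the FE grid: block-mean occupancy > 0.5.
downsample_mask <- function(mask, spacing, target_spacing) {
  dm <- downsample_density(density_image(mask * 1.0, spacing),
                           target_spacing)
  dm$density > 0.5
}

#' Run a full synthetic two-arm study
#'
#' Orchestrates generate, calibrate, segment, morphometry, virtual
#' torsion, biomechanics, and the group report for one study. With
#' `image_stages = TRUE` every subject's operated tibia is rendered as a
#' synthetic scan and pushed through the image pipeline; otherwise
#' morphometry comes from the sampled ground truth and VTR from the
#' analytic surrogate. Subjects whose virtual structure is discontinuous
#' (nonunion analogue) or whose torsion trace never reaches the regression
#' window carry `NA` for those endpoints and are flagged.
#'
#' @param config `ovtr_config` from [run_config()].
#' @return List with `subjects` (per-subject data.frame), `comparisons`
#'   (group table), `calibration`, and `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "ovtr_config"))
  specs <- if (config$model == "17mm") arm_specs_17mm() else arm_specs_3mm()
  design <- study_design(config$n_per_arm, specs, seed = config$seed)
  subjects <- sample_study(design)
  n <- nrow(subjects)
  subseeds <- with_seed(config$seed + 1, sample.int(.Machine$integer.max, 3 * n))

  phantom <- make_phantom_scan(config$rod_densities, config$calibration,
                               noise_sd = config$hu_noise_sd,
                               spacing = max(config$spacing, 0.4),
                               seed = subseeds[3 * n])
  cal <- fit_calibration(phantom)

  geom <- config$geometry
  gap <- geom$gap_width
  roi <- c(-(gap / 2 + 10), gap / 2 + 10)

  vtr_nonop <- if (config$image_stages) {
    intact <- make_tibia_scan(
      scan_geometry(geom$outer_radius, geom$cortical_thickness,
                    geom$bone_length, gap_width = 0,
                    voxel_spacing = config$spacing),
      callus_spec(0, 700), calibration = config$calibration,
      noise_sd = config$hu_noise_sd, seed = subseeds[3 * n - 1])
    dens_i <- downsample_density(apply_calibration(intact, cal),
                                 config$fe_spacing)
    keep_i <- downsample_mask(intact$truth$body, config$spacing,
                              config$fe_spacing)
    simulate_torsion(build_fe_model(dens_i, config$material, keep_i),
                     tol = config$fe_tol)$vtr
  } else {
    vtr_surrogate_intact(geom, config$material)
  }

  res <- lapply(seq_len(n), function(i) {
    s <- subjects[i, ]
    out <- list(callus_volume = NA_real_, callus_density = NA_real_,
                vtr_op = NA_real_, nonunion = FALSE,
                rigidity_op = NA_real_, rigidity_nonop = NA_real_,
                window_unreachable = FALSE)
    if (config$image_stages) {
      scan <- make_tibia_scan(
        geom, callus_spec(s$callus_volume, s$callus_density),
        calibration = config$calibration, noise_sd = config$hu_noise_sd,
        seed = subseeds[3 * i - 2])
      dens <- apply_calibration(scan, cal)
      seg <- segment_callus(dens, scan$truth$old_bone, roi = roi,
                            mineralization_threshold =
                              config$mineralization_threshold,
                            min_component = config$min_component)
      morpho <- compute_morphometry(seg, dens)
      out$callus_volume <- morpho$callus_volume
      out$callus_density <- morpho$callus_density
      dens_fe <- downsample_density(dens, config$fe_spacing)
      keep <- downsample_mask(scan$truth$body, config$spacing,
                              config$fe_spacing)
      out$vtr_op <- tryCatch(
        simulate_torsion(build_fe_model(dens_fe, config$material, keep),
                         tol = config$fe_tol)$vtr,
        ovtr_discontinuous = function(e) { out$nonunion <<- TRUE; NA_real_ })
    } else {
      out$callus_volume <- s$callus_volume
      out$callus_density <- s$callus_density
      out$vtr_op <- vtr_surrogate(s$callus_volume, s$callus_density, geom,
                                  config$material)
    }
    # biomechanics: synthetic torsion traces from the sampled rigidities
    k_op <- s$op_rigidity * 1000 / config$gauge_length
    k_non <- s$nonop_rigidity * 1000 / config$gauge_length
    tr_op <- make_torsion_trace(k_op, noise_sd = config$trace_noise_sd,
                                toe_region = config$toe_region,
                                seed = subseeds[3 * i - 1])
    tr_non <- make_torsion_trace(k_non, noise_sd = config$trace_noise_sd,
                                 toe_region = config$toe_region,
                                 seed = subseeds[3 * i])
    out$rigidity_nonop <- tryCatch(
      analyze_trace(tr_non, config$gauge_length, config$window)$rigidity,
      ovtr_window_unreachable = function(e) NA_real_)
    out$rigidity_op <- tryCatch(
      analyze_trace(tr_op, config$gauge_length, config$window)$rigidity,
      ovtr_window_unreachable = function(e) {
        out$window_unreachable <<- TRUE; NA_real_ })
    as.data.frame(out)
  })
  res <- do.call(rbind, res)
  subjects <- cbind(subjects, res)
  subjects$vtr_nonop <- vtr_nonop
  subjects$normalized_vtr <- ifelse(
    is.na(subjects$vtr_op), NA_real_,
    100 * subjects$vtr_op / subjects$vtr_nonop)
  subjects$normalized_rigidity <- ifelse(
    is.na(subjects$rigidity_op) | is.na(subjects$rigidity_nonop), NA_real_,
    100 * subjects$rigidity_op / subjects$rigidity_nonop)

  # test assignment mirrors the study's reporting: parametric for
  # morphometry and VTR, nonparametric for biomechanics
  override <- c(callus_volume = "t", callus_density = "t", vtr_op = "t",
                normalized_vtr = "t",
                rigidity_op = "mann_whitney",
                rigidity_nonop = "mann_whitney",
                normalized_rigidity = "mann_whitney")
  comparisons <- group_table(
    subjects,
    parameters = c("callus_volume", "callus_density", "vtr_op",
                   "normalized_vtr", "rigidity_op", "rigidity_nonop",
                   "normalized_rigidity"),
    test_override = override, seed = config$seed)

  manifest <- list(package_version = as.character(utils::packageVersion("ovtr")),
                   seed = config$seed, model = config$model,
                   n_per_arm = config$n_per_arm,
                   config_hash = config_hash(config),
                   image_stages = config$image_stages,
                   calibration_fit = unclass(cal),
                   truncation_redraws = attr(subjects, "truncation_redraws"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(subjects, file.path(config$out_dir, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(config$out_dir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(subjects = subjects, comparisons = comparisons, calibration = cal,
       manifest = manifest)
}
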