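test_that("phantom rods realise the HU line exactly without noise", {
  # identity mapping
  ph <- make_phantom_scan(c(0, 800), calibration = c(1, 0), noise_sd = 0)
  means <- vapply(1:2, function(i) mean(ph$hu[ph$truth$rod_label == i]),
                  numeric(1))
  expect_equal(means, c(0, 800))
  # direct evaluation of slope * rho + intercept
  ph2 <- make_phantom_scan(c(100, 400, 800), calibration = c(1.2, -50),
                           noise_sd = 0)
  means2 <- vapply(1:3, function(i) mean(ph2$hu[ph2$truth$rod_label == i]),
                   numeric(1))
  expect_equal(means2, c(70, 430, 910))
})

test_that("noisy phantom rod means satisfy the CLT bound", {
  ph <- make_phantom_scan(c(200, 1000), calibration = c(1, 0), noise_sd = 20,
                          spacing = 0.2, seed = 4)
  for (i in 1:2) {
    sel <- ph$truth$rod_label == i
    n_vox <- sum(sel)
    expect_gte(n_vox, 1000)
    bound <- 3 * 20 / sqrt(n_vox)
    expect_lt(abs(mean(ph$hu[sel]) - c(200, 1000)[i]), max(bound, 2))
  }
})

test_that("phantom with fewer than two distinct rods is rejected", {
  expect_error(make_phantom_scan(800), class = "ovtr_invalid_input")
  expect_error(make_phantom_scan(c(500, 500)), class = "ovtr_invalid_input")
})

test_that("intact tibia has no callus and a full cortical tube", {
  g <- scan_geometry(gap_width = 0, voxel_spacing = 0.8, bone_length = 30)
  scan <- make_tibia_scan(g, callus_spec(0, 700))
  expect_false(any(scan$truth$callus))
  # every slice carries the same annulus
  per_slice <- apply(scan$truth$old_bone, 3, sum)
  expect_true(all(per_slice == per_slice[1]))
  expect_gt(per_slice[1], 0)
})

test_that("callus truth volume and density hit the generator set-points", {
  g <- small_geometry(gap = 17, spacing = 0.5)
  scan <- make_tibia_scan(g, callus_spec(12.0, 762, density_noise_sd = 0))
  vol <- scan$truth$callus_volume_cm3
  expect_lt(abs(vol - 12.0) / 12.0, 0.02)
  expect_equal(mean(scan$truth$density[scan$truth$callus]), 762)
  # masks disjoint and on the shared grid
  expect_false(any(scan$truth$callus & scan$truth$old_bone))
  expect_identical(dim(scan$truth$callus), dim(scan$hu))
})

test_that("tibia generation is a pure function of its seed", {
  g <- small_geometry(spacing = 0.8)
  cs <- callus_spec(4, 700, density_noise_sd = 30)
  a <- make_tibia_scan(g, cs, noise_sd = 15, seed = 99)
  b <- make_tibia_scan(g, cs, noise_sd = 15, seed = 99)
  expect_identical(a$hu, b$hu)
  c <- make_tibia_scan(g, cs, noise_sd = 15, seed = 100)
  expect_false(identical(a$hu, c$hu))
})

test_that("unachievable callus volume raises a capacity error", {
  g <- small_geometry(spacing = 0.8)
  expect_error(make_tibia_scan(g, callus_spec(200, 700)),
               class = "ovtr_capacity_error")
})

test_that("torsion trace respects caps and sampling geometry", {
  # torque cap: last sample is the first at or above 10 Nm
  tr <- make_torsion_trace(1.25, toe_region = 0)
  expect_gte(tr$torque[length(tr$torque)], 10)
  expect_true(all(tr$torque[-length(tr$torque)] < 10))
  expect_lte(max(tr$rotation), 12)
  # angle cap binds when the torque cap is unreachable (0.5 * 12 = 6 < 10)
  tr2 <- make_torsion_trace(0.5, toe_region = 0)
  expect_equal(max(tr2$rotation), 12)
  expect_equal(max(tr2$torque), 6)
  # rotation increment = rate / (60 * sampling)
  expect_equal(diff(tr$rotation)[1], 5 / (60 * 20))
  expect_true(!is.unsorted(tr$rotation))
  # determinism
  n1 <- make_torsion_trace(1, noise_sd = 0.05, seed = 5)
  n2 <- make_torsion_trace(1, noise_sd = 0.05, seed = 5)
  expect_identical(n1$torque, n2$torque)
})

test_that("study sampling is reproducible and converges to the arm specs", {
  d <- study_design(6, arm_specs_17mm(), seed = 21)
  s1 <- sample_study(d)
  s2 <- sample_study(d)
  expect_identical(s1$callus_volume, s2$callus_volume)
  expect_identical(s1$arm, s1$arm)

  # degenerate SD 0 pins every subject at the mean
  sp0 <- arm_specs_17mm()
  for (arm in names(sp0)) for (q in names(sp0[[arm]]))
    sp0[[arm]][[q]]["sd"] <- 0
  s0 <- sample_study(study_design(4, sp0, seed = 1))
  expect_true(all(s0$callus_volume[s0$arm == "Control"] == 7.3))
  expect_true(all(s0$callus_density[s0$arm == "CEMF"] == 762))

  # large-n empirical mean within the standard-error bound
  big <- sample_study(study_design(10000, arm_specs_17mm(), seed = 2))
  vol_ctrl <- big$callus_volume[big$arm == "Control"]
  expect_lt(abs(mean(vol_ctrl) - 7.3), 0.05)
  expect_lt(abs(sd(vol_ctrl) - 1.3), 3 * 1.3 / sqrt(2 * 10000))
})

test_that("truncation keeps strictly positive quantities positive", {
  sp <- arm_specs_17mm()
  sp$Control$op_rigidity <- c(mean = 0.05, sd = 0.5)   # mostly negative mass
  s <- sample_study(study_design(200, sp, seed = 3))
  expect_true(all(s$op_rigidity > 0))
  expect_gt(attr(s, "truncation_redraws"), 0)
})
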