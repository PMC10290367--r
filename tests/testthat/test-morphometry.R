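test_that("volume arithmetic and empty-mask conventions hold", {
  d <- density_image(array(700, c(10, 10, 10)), spacing = 1)
  mask <- array(TRUE, c(10, 10, 10))
  m <- compute_morphometry(mask, d)
  expect_equal(m$callus_volume, 1.000)      # 1000 voxels at 1 mm = 1 cm^3
  expect_equal(m$callus_density, 700)       # uniform density -> exact mean
  empty <- array(FALSE, c(10, 10, 10))
  m0 <- compute_morphometry(empty, d)
  expect_equal(m0$callus_volume, 0)
  expect_true(is.na(m0$callus_density))     # undefined, not 0
})

test_that("volume is additive over disjoint masks", {
  d <- density_image(array(runif(8^3, 400, 900), c(8, 8, 8)), spacing = 0.5)
  a <- array(FALSE, c(8, 8, 8)); a[1:4, , ] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[5:8, , 1:3] <- TRUE
  va <- compute_morphometry(a, d)$callus_volume
  vb <- compute_morphometry(b, d)$callus_volume
  vab <- compute_morphometry(a | b, d)$callus_volume
  expect_equal(vab, va + vb)
})

test_that("segmentation on an intact tube or absurd threshold is empty", {
  g <- small_geometry(gap = 0, spacing = 0.8)
  scan <- make_tibia_scan(g, callus_spec(0, 700))
  dens <- apply_calibration(scan, identity_calibration())
  seg <- segment_callus(dens, scan$truth$old_bone)
  expect_false(any(seg$callus_mask))
  g2 <- small_geometry(gap = 3, spacing = 0.8)
  scan2 <- make_tibia_scan(g2, callus_spec(2, 700, density_noise_sd = 0))
  dens2 <- apply_calibration(scan2, identity_calibration())
  seg2 <- segment_callus(dens2, scan2$truth$old_bone,
                         mineralization_threshold = 2000)
  expect_false(any(seg2$callus_mask))
})

test_that("raising the mineralization threshold never grows the callus", {
  g <- small_geometry(spacing = 0.8)
  scan <- make_tibia_scan(g, callus_spec(4, 700, density_noise_sd = 60),
                          noise_sd = 25, seed = 8)
  dens <- apply_calibration(scan, identity_calibration())
  vols <- vapply(c(300, 450, 600, 700, 800), function(th) {
    seg <- segment_callus(dens, scan$truth$old_bone,
                          mineralization_threshold = th)
    compute_morphometry(seg, dens)$callus_volume
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("noiseless synthetic scans are recovered to discretisation error", {
  g <- small_geometry(gap = 17, spacing = 0.5)
  scan <- make_tibia_scan(g, callus_spec(12.0, 762, density_noise_sd = 0))
  dens <- apply_calibration(scan, identity_calibration())
  seg <- segment_callus(dens, scan$truth$old_bone, roi = c(-18.5, 18.5))
  m <- compute_morphometry(seg, dens)
  expect_lt(abs(m$callus_volume - 12.0) / 12.0, 0.02)
  expect_lt(abs(m$callus_density - 762) / 762, 0.02)
  expect_gte(dice(seg$callus_mask, scan$truth$callus), 0.99)
})

test_that("segmentation survives 30 HU of scanner noise (Dice >= 0.95)", {
  g <- small_geometry(gap = 17, spacing = 0.5)
  scan <- make_tibia_scan(g, callus_spec(12.0, 762, density_noise_sd = 30),
                          noise_sd = 30, seed = 12)
  dens <- apply_calibration(scan, identity_calibration())
  seg <- segment_callus(dens, scan$truth$old_bone, roi = c(-18.5, 18.5))
  expect_gte(dice(seg$callus_mask, scan$truth$callus), 0.95)
})

test_that("component cleanup removes small islands", {
  rho <- array(0, c(20, 20, 20))
  rho[5:14, 5:14, 5:14] <- 700        # 1000-voxel block
  rho[18, 18, 18] <- 700              # isolated voxel
  d <- density_image(rho, 1)
  none <- array(FALSE, dim(rho))
  seg <- segment_callus(d, none, min_component = 50)
  expect_equal(sum(seg$callus_mask), 1000)
  seg2 <- segment_callus(d, none, min_component = 1)
  expect_equal(sum(seg2$callus_mask), 1001)
})

test_that("grid mismatches and empty ROIs are explicit errors", {
  d <- density_image(array(0, c(4, 4, 4)), 1)
  expect_error(segment_callus(d, array(FALSE, c(5, 4, 4))),
               class = "ovtr_grid_mismatch")
  expect_error(segment_callus(d, array(FALSE, c(4, 4, 4)), roi = c(50, 60)),
               class = "ovtr_invalid_input")
  expect_error(compute_morphometry(array(FALSE, c(3, 3, 3)), d),
               class = "ovtr_grid_mismatch")
})
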