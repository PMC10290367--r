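test_that("pooled t test matches its closed form and conventions", {
  r <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # shift by 10 with pooled SD 1: |t| = 10 / sqrt(2/3)
  r2 <- students_t(c(1, 2, 3), c(11, 12, 13))
  expect_equal(abs(r2$t), 10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_lt(r2$p, 0.001)
  expect_equal(r2$df, 4)
  # agreement with the reference implementation
  set.seed(7)
  a <- rnorm(8); b <- rnorm(9, 0.5)
  ref <- t.test(a, b, var.equal = TRUE)
  mine <- students_t(a, b)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # zero-variance conventions
  expect_equal(students_t(c(2, 2), c(2, 2))$p, 1)
  expect_equal(students_t(c(2, 2), c(3, 3))$p, 0)
})

test_that("Cohen's d reproduces the published effect sizes", {
  # 17-mm VTR: 0.32 +/- 0.27 vs 0.90 +/- 0.33, n = 6 + 6 -> d = 1.93
  d_vtr <- cohens_d_summary(0.32, 0.27, 6, 0.90, 0.33, 6)
  expect_lt(abs(d_vtr - 1.93) / 1.93, 0.01)
  # 17-mm biomechanical rigidity: 0.32 +/- 0.31 vs 0.85 +/- 0.37 -> d = 1.54
  d_rig <- cohens_d_summary(0.32, 0.31, 6, 0.85, 0.37, 6)
  expect_lt(abs(d_rig - 1.54) / 1.54, 0.01)
  # antisymmetry
  expect_equal(cohens_d_summary(0.90, 0.33, 6, 0.32, 0.27, 6), -d_vtr)
  # raw-sample and summary paths agree exactly
  set.seed(3)
  a <- rnorm(6); b <- rnorm(6, 1)
  expect_equal(cohens_d(a, b),
               cohens_d_summary(mean(a), sd(a), 6, mean(b), sd(b), 6),
               tolerance = 1e-12)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
})

test_that("Levene's test detects variance differences and nothing else", {
  expect_equal(levene_test(c(1, 2, 3), c(3, 1, 2))$W, 0)
  expect_equal(levene_test(c(1, 2, 3), c(3, 1, 2))$p, 1)
  # location invariance
  set.seed(11)
  a <- rnorm(20); b <- rnorm(20, 0, 3)
  r1 <- levene_test(a, b)
  r2 <- levene_test(a + 100, b)
  expect_equal(r1$W, r2$W, tolerance = 1e-9)
  # variance ratio 100 at n = 50 is flagged
  a2 <- rnorm(50, 0, 1); b2 <- rnorm(50, 0, 10)
  expect_lt(levene_test(a2, b2)$p, 0.01)
  # cross-check against car's mean-centred Levene when available
  if (requireNamespace("car", quietly = TRUE)) {
    ref <- car::leveneTest(c(a, b), factor(rep(1:2, each = 20)),
                           center = mean)
    expect_equal(r1$W, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(r1$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
})

test_that("Lilliefors KS statistic matches nortest and bounds hold", {
  set.seed(5)
  x <- rnorm(40)
  r <- ks_normality(x, seed = 1)
  expect_gte(r$D, 0); expect_lte(r$D, 1)
  expect_gte(r$p, 0); expect_lte(r$p, 1)
  if (requireNamespace("nortest", quietly = TRUE)) {
    expect_equal(r$D, unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
  # constant sample is non-normal by convention
  expect_equal(ks_normality(rep(1, 5))$p, 0)
})

test_that("KS normality rejects exponential samples with high power", {
  rej <- vapply(1:20, function(s) {
    x <- ovtr:::with_seed(s, rexp(100))
    ks_normality(x, n_mc = 400, seed = 1000 + s)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("Mann-Whitney U and exact p match enumeration oracles", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)            # 2 / 20 labelings
  expect_equal(r$method, "exact")
  # identical samples give p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # tie-free 6+6: agreement with wilcox.test's exact distribution
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6, runif(1, -1, 1))
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    mine <- mann_whitney_u(a, b)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  # tied integer data: agreement with brute-force permutation enumeration
  cases <- list(
    list(a = c(1, 2, 2, 3, 5), b = c(2, 3, 3, 4, 4)),
    list(a = c(0, 0, 1, 1, 2), b = c(1, 2, 2, 2, 3)),
    list(a = c(5, 5, 5, 1, 2), b = c(5, 5, 2, 2, 2))
  )
  for (cs in cases) {
    expect_equal(mann_whitney_u(cs$a, cs$b)$p, mw_bruteforce_p(cs$a, cs$b),
                 tolerance = 1e-12)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(23)
  a <- rnorm(30); b <- rnorm(30, 0.8)
  mine <- mann_whitney_u(a, b)
  expect_equal(mine$method, "normal")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("test selection follows the normality and variance screens", {
  set.seed(31)
  a <- rnorm(30); b <- rnorm(30, 0.2)
  expect_equal(as.character(choose_test(a, b, seed = 1)), "t")
  skew <- rexp(30)
  sel <- choose_test(a, skew, seed = 1)
  expect_equal(as.character(sel), "mann_whitney")
  expect_true(any(attr(sel, "diagnostics") < 0.05))
  # deterministic given the seed
  expect_identical(as.character(choose_test(a, b, seed = 9)),
                   as.character(choose_test(a, b, seed = 9)))
})

test_that("group tables are symmetric under arm exchange", {
  set.seed(41)
  rec <- data.frame(
    arm = rep(c("Control", "CEMF"), each = 6),
    vol = c(rnorm(6, 7.3, 1.3), rnorm(6, 12, 2.3)),
    dens = c(rnorm(6, 674, 82), rnorm(6, 762, 56))
  )
  t1 <- group_table(rec, c("vol", "dens"),
                    test_override = c(vol = "t", dens = "mann_whitney"),
                    arms = c("Control", "CEMF"))
  t2 <- group_table(rec, c("vol", "dens"),
                    test_override = c(vol = "t", dens = "mann_whitney"),
                    arms = c("CEMF", "Control"))
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  expect_equal(t1$cohens_d, -t2$cohens_d, tolerance = 1e-12)
})

test_that("missing values are excluded pairwise and counted", {
  rec <- data.frame(
    arm = rep(c("Control", "CEMF"), each = 4),
    x = c(1, 2, NA, 3, 5, 6, 7, NA)
  )
  tab <- group_table(rec, "x", test_override = c(x = "t"))
  expect_equal(tab$n_missing, 2)
  expect_false(is.na(tab$p))
})
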