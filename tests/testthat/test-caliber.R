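test_that("an empty mask yields an empty sample list", {
  m <- pa_volume(array(FALSE, c(10, 10, 10)), 0.125)
  df <- measure_diameters(m)
  expect_equal(nrow(df), 0)
  expect_named(df, c("x_mm", "y_mm", "z_mm", "diameter_mm", "deviation_vox"))
})

test_that("anisotropic spacing is rejected", {
  m <- pa_volume(array(TRUE, c(4, 4, 4)), c(0.125, 0.125, 0.25))
  expect_error(measure_diameters(m), "isotropic")
})

test_that("a straight cylinder gives one measurement near its diameter", {
  tree <- cylinder_tree(0.4, depth_mm = 2)
  cfg <- quiet_config()
  m <- render_clean_mask(tree, cfg)
  df <- measure_diameters(m)
  expect_equal(nrow(df), 1)
  expect_lt(abs(df$diameter_mm - 0.4), 0.25)
  expect_lte(df$deviation_vox, 1)
})

test_that("no measurement falls inside the bifurcation exclusion zone", {
  # Y-shaped vessel: trunk along x, two arms splitting at (6, 6, 2)
  ext <- c(14, 14, 20)
  junction <- c(6, 6.06, 2)
  trunk <- cbind(seq(1.5, junction[1], 0.25), junction[2], 2)
  arm1 <- cbind(seq(junction[1], 12, 0.25),
                junction[2] + (seq(junction[1], 12, 0.25) - junction[1]) * 0.6, 2)
  arm2 <- cbind(seq(junction[1], 12, 0.25),
                junction[2] - (seq(junction[1], 12, 0.25) - junction[1]) * 0.6, 2)
  tree <- manual_tree(list(trunk, arm1, arm2), c(0.4, 0.4, 0.4), ext, 0.125)
  m <- render_clean_mask(tree, quiet_config(ext))
  df <- measure_diameters(m)
  expect_gt(nrow(df), 0)
  # exclusion radius is 2 x local diameter (~0.8 mm); allow the skeleton
  # junction to sit up to ~2 voxels off the geometric fork
  dist_to_fork <- sqrt((df$x_mm - junction[1])^2 + (df$y_mm - junction[2])^2 +
                         (df$z_mm - junction[3])^2)
  expect_true(all(dist_to_fork > 0.8 - 2 * 0.125))
})

test_that("cutoff derivation interpolates order statistics and rounds half-up", {
  cs <- derive_cutoffs(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(cs$q1, 0.175)
  expect_equal(cs$median, 0.25)
  expect_equal(cs$q3, 0.325)
  expect_equal(cs$lower, 0.2)
  expect_equal(cs$upper, 0.3)
  expect_equal(cs$n, 4)
  expect_error(derive_cutoffs(rep(0.4, 10)), "degenerate")
  expect_error(derive_cutoffs(c(0.1, 0.2)), "at least 4")
})

test_that("the pooled synthetic sample reproduces the rounded cutoffs", {
  d <- sample_diameters(2008, seed = 1)
  cs <- derive_cutoffs(d)
  expect_equal(cs$lower, 0.3)
  expect_equal(cs$upper, 0.5)
  expect_lt(abs(cs$q1 - 0.29), 0.01)
  expect_lt(abs(cs$median - 0.37), 0.01)
  expect_lt(abs(cs$q3 - 0.50), 0.01)
})

test_that("quartiles match the sort-and-interpolate oracle exactly", {
  set.seed(55)
  for (i in 1:100) {
    x <- round(runif(sample(4:60, 1), 0.08, 1.3), 3)
    if (max(x) == min(x)) x[1] <- x[1] + 0.1
    q <- tryCatch(derive_cutoffs(x), error = function(e) NULL)
    if (is.null(q)) next # degenerate rounded cutoffs are allowed to error
    expect_equal(c(q$q1, q$median, q$q3), unname(oracle_quartiles(x)),
                 tolerance = 1e-12)
  }
})

test_that("classification is boundary-inclusive to medium", {
  cs <- derive_cutoffs(sample_diameters(2008, seed = 1)) # cutoffs 0.3 / 0.5
  expect_equal(as.character(classify_diameter(0.3, cs)), "medium")
  expect_equal(as.character(classify_diameter(0.5, cs)), "medium")
  expect_equal(as.character(classify_diameter(0.29, cs)), "small")
  expect_equal(as.character(classify_diameter(0.51, cs)), "large")
  expect_error(classify_diameter(0.07, cs), "range")
  expect_error(classify_diameter(1.31, cs), "range")
  # partition property: every measurable diameter lands in exactly one class
  grid <- seq(0.08, 1.3, by = 0.005)
  cls <- classify_diameter(grid, cs)
  expect_false(any(is.na(cls)))
  expect_equal(sort(unique(as.character(cls))), c("large", "medium", "small"))
})

test_that("class proportions normalise and respect order invariance", {
  cs <- derive_cutoffs(c(0.1, 0.25, 0.45, 0.8))  # cutoffs 0.2 / 0.5
  s <- data.frame(diameter_mm = c(0.15, 0.4, 0.6))
  p <- caliber_proportions(s, cs)
  expect_equal(unlist(p[, c("small", "medium", "large")]),
               c(small = 1, medium = 1, large = 1) / 3)
  expect_equal(p$small + p$medium + p$large, 1)

  s2 <- data.frame(diameter_mm = rep(0.1, 5))
  p2 <- caliber_proportions(s2, cs)
  expect_equal(c(p2$small, p2$medium, p2$large), c(1, 0, 0))

  set.seed(66)
  s3 <- data.frame(diameter_mm = runif(50, 0.08, 1.3),
                   case = sample(c("a", "b"), 50, TRUE),
                   side = sample(c("reconstructed", "contralateral"), 50, TRUE))
  p3 <- caliber_proportions(s3, cs)
  p3r <- caliber_proportions(s3[sample(50), ], cs)
  expect_equal(p3, p3r)
  expect_true(all(abs(p3$small + p3$medium + p3$large - 1) < 1e-9))
})

test_that("rendered cylinders are recovered across the caliber range", {
  errs <- c()
  for (d0 in c(0.2, 0.4, 0.8)) {
    for (s in 1:2) {
      set.seed(400 + s)
      tree <- cylinder_tree(d0, depth_mm = 2,
                            y_mm = 6 + runif(1, -0.06, 0.06))
      m <- render_clean_mask(tree, quiet_config())
      df <- measure_diameters(m)
      expect_gt(nrow(df), 0)
      errs <- c(errs, abs(median(df$diameter_mm) - d0))
    }
  }
  expect_true(all(errs <= 0.25))
  expect_lte(mean(errs), 2 * 0.125)
})
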