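test_that("case generation is bit-reproducible from one seed", {
  cr <- phantom_config("reconstructed", spacing_mm = 0.5)
  cc <- phantom_config("contralateral", spacing_mm = 0.5)
  b1 <- make_case(cr, cc, interval_months = 12, seed = 9)
  b2 <- make_case(cr, cc, interval_months = 12, seed = 9)
  expect_identical(b1$reconstructed$volume$data, b2$reconstructed$volume$data)
  expect_identical(b1$contralateral$volume$data, b2$contralateral$volume$data)
  expect_identical(b1$reconstructed$tree$segments, b2$reconstructed$tree$segments)
})

test_that("a zero length budget yields an empty tree", {
  cfg <- phantom_config("contralateral", spacing_mm = 0.5, length_budget_mm = 0)
  tree <- generate_vessel_tree(cfg, seed = 1)
  expect_length(tree$segments, 0)
  expect_equal(tree$total_length_mm, 0)
})

test_that("an unreachable coverage target is a generation error", {
  cfg <- phantom_config("contralateral", spacing_mm = 0.5, length_budget_mm = 30)
  expect_error(generate_vessel_tree(cfg, seed = 1), "length budget")
})

test_that("all node diameters lie in the anchor range", {
  for (side in c("contralateral", "reconstructed")) {
    cfg <- phantom_config(side, spacing_mm = 0.5, interval_months = 30)
    tree <- generate_vessel_tree(cfg, seed = 2)
    d <- unlist(lapply(tree$segments, `[[`, "diameter_mm"))
    expect_true(all(d >= 0.08 & d <= 1.3))
  }
})

test_that("the reconstructed side carries more superficial centerline", {
  cr <- phantom_config("reconstructed", spacing_mm = 0.5)
  cc <- phantom_config("contralateral", spacing_mm = 0.5)
  tr <- generate_vessel_tree(cr, seed = 3)
  tc <- generate_vessel_tree(cc, seed = 3)
  expect_gt(tree_length_in_slab(tr, 0, 2.5), tree_length_in_slab(tc, 0, 2.5))
})

test_that("a zero interval leaves the reconstructed anchors unshifted", {
  cfg <- phantom_config("reconstructed", interval_months = 0)
  expect_equal(effective_anchors(cfg)$diameters, cfg$anchors$diameters)
  cfg30 <- phantom_config("reconstructed", interval_months = 30)
  expect_true(all(effective_anchors(cfg30)$diameters <= cfg30$anchors$diameters))
})

test_that("an empty tree renders to sub-1% binarised foreground", {
  cfg <- phantom_config("contralateral", extent_mm = c(20, 20, 20),
                        spacing_mm = 0.5, coverage = 0)
  tree <- generate_vessel_tree(cfg, seed = 1)
  set.seed(5)
  vol <- render_volume(tree, cfg)
  m <- binarize(to_grayscale(vol))
  expect_lt(mean(m$data), 0.01)
})

test_that("attenuation makes vessel intensity decrease with depth", {
  ext <- c(12, 12, 20)
  tree <- manual_tree(list(cbind(seq(2, 10, 0.5), 6.06, 1),
                           cbind(seq(2, 10, 0.5), 6.06, 15)),
                      c(0.6, 0.6), ext, 0.125)
  base <- quiet_config(ext, 0.125, mu_eff = 0, noise_sd = 1e-6)
  set.seed(7)
  v0 <- render_volume(tree, base)
  sh <- v0$data[, , 1:24]   # around depth 1 mm
  dp <- v0$data[, , 113:136] # around depth 15 mm
  expect_equal(mean(sh[sh > 75]), mean(dp[dp > 75]), tolerance = 0.01)

  att <- quiet_config(ext, 0.125, mu_eff = 0.15, noise_sd = 1e-6)
  set.seed(7)
  v1 <- render_volume(tree, att)
  sh1 <- v1$data[, , 1:24]; dp1 <- v1$data[, , 113:136]
  # vessel voxels sit above the tissue baseline (28) on both slabs
  expect_gt(mean(sh1[sh1 > 45]), mean(dp1[dp1 > 45]) + 50)
})

test_that("the direct mask render matches the intensity pipeline in rate", {
  cfg <- phantom_config("contralateral", extent_mm = c(20, 20, 20),
                        spacing_mm = 0.25)
  tree <- generate_vessel_tree(cfg, seed = 31)
  set.seed(32)
  full <- binarize(to_grayscale(render_volume(tree, cfg)))
  fast <- render_mask(tree, cfg)
  expect_equal(dim(fast$data), dim(full$data))
  # same model, different realisation: foreground rates agree closely
  expect_equal(mean(fast$data), mean(full$data), tolerance = 0.02)
  # per-slice rates agree in the superficial half too
  r_fast <- apply(fast$data[, , 1:40], 3, mean)
  r_full <- apply(full$data[, , 1:40], 3, mean)
  expect_lt(max(abs(r_fast - r_full)), 0.05)
})

test_that("a contact defect displaces the affected columns", {
  cfg <- phantom_config("contralateral", extent_mm = c(20, 20, 20),
                        spacing_mm = 0.5, coverage = 0.1,
                        contact_defect = list(gap_mm = 3, fraction = 0.25))
  tree <- generate_vessel_tree(cfg, seed = 8)
  set.seed(8)
  vol <- render_volume(tree, cfg)
  gap_vox <- round(3 / 0.5)
  defect_cols <- vol$data[1:9, , 1:gap_vox] # x < 5 mm
  expect_true(all(defect_cols == 0))
  sound_cols <- vol$data[15:40, , 1:gap_vox]
  expect_gt(mean(sound_cols), 10)
})
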