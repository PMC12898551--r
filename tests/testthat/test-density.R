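test_that("grayscale conversion is a rounded min-max map", {
  a <- array(0L, c(4, 4, 2)); a[1] <- 255L
  vol <- pa_volume(a, 1)
  expect_identical(to_grayscale(vol)$data, a) # already full-range 8-bit

  const <- pa_volume(array(7.5, c(3, 3, 3)), 1)
  expect_true(all(to_grayscale(const)$data == 0L))

  f <- pa_volume(array(c(0, 0.5, 1, 0.25), c(2, 2, 1)), 1)
  g <- to_grayscale(f)
  expect_equal(g$data[2, 1, 1], 128L) # 127.5 rounds half-up
  expect_equal(g$data[1, 2, 1], 255L)
  expect_equal(g$data[1, 1, 1], 0L)
})

test_that("binarisation is strictly above-threshold", {
  a <- array(75L, c(5, 5, 2))
  vol <- pa_volume(a, 1)
  expect_equal(sum(binarize(vol)$data), 0)
  a[2, 3, 1] <- 76L
  expect_equal(sum(binarize(pa_volume(a, 1))$data), 1)
  set.seed(9)
  b <- array(0L, c(10, 10, 1))
  b[sample(100, 28)] <- 200L
  expect_equal(mean(binarize(pa_volume(b, 1))$data), 0.28)
  expect_error(binarize(vol, threshold = 300), "\\[0, 255\\]")
})

test_that("depth-layer assignment uses half-open intervals", {
  expect_equal(assign_depth_layer(c(0, 2.5, 2.49, 5, 17.5, 19.99)),
               c(1L, 2L, 1L, 3L, 8L, 8L))
  expect_true(is.na(assign_depth_layer(20)))
  expect_true(is.na(assign_depth_layer(-0.1)))
})

test_that("an all-background ROI yields a profile of zeros", {
  m <- pa_volume(array(FALSE, c(8, 8, 40)), 0.5)
  prof <- density_profile(list(m))
  expect_equal(prof$density_pct, rep(0, 8))
})

test_that("density equals the brute-force per-voxel oracle exactly", {
  set.seed(41)
  for (rep in 1:6) {
    d <- c(sample(6:12, 2, replace = TRUE), 40)
    dz <- 0.5
    mask <- array(runif(prod(d)) < runif(1, 0.05, 0.4), d)
    off <- matrix(sample(c(0, 0.5, 1), d[1] * d[2], replace = TRUE), d[1], d[2])
    vol <- pa_volume(mask, dz)
    for (meth in c("voxel", "projection")) {
      prof <- density_profile(list(vol), list(off), method = meth)
      orc <- if (meth == "voxel") oracle_density_voxel(mask, dz, off)
             else oracle_density_projection(mask, dz, off)
      expect_identical(prof$density_pct, orc$pct)
      expect_identical(prof$foreground, orc$fg)
      expect_identical(prof$total, orc$tot)
    }
  }
})

test_that("layer voxel counts conserve the in-range total", {
  set.seed(42)
  d <- c(10, 10, 44) # 22 mm depth at 0.5 mm: some voxels beyond 20 mm
  mask <- array(runif(prod(d)) < 0.2, d)
  off <- matrix(0.5, d[1], d[2])
  prof <- density_profile(list(pa_volume(mask, 0.5)), list(off), method = "voxel")
  depths <- rep((seq_len(d[3]) - 0.5) * 0.5 - 0.5, each = d[1] * d[2])
  expect_equal(sum(prof$total), sum(depths >= 0 & depths < 20))
})

test_that("pooled density is invariant to ROI order", {
  set.seed(43)
  rois <- lapply(1:3, function(i)
    pa_volume(array(runif(8 * 8 * 40) < 0.3, c(8, 8, 40)), 0.5))
  p1 <- density_profile(rois)
  p2 <- density_profile(rev(rois))
  expect_equal(p1$density_pct, p2$density_pct)
})

test_that("layers with no voxels are an error, not silent zeros", {
  shallow <- pa_volume(array(FALSE, c(6, 6, 10)), 0.5) # only 5 mm deep
  expect_error(density_profile(list(shallow)), "undefined density")
})

test_that("paired profiles decrease with depth and order the sides", {
  l1r <- numeric(2); l1c <- numeric(2)
  for (i in 1:2) {
    cr <- phantom_config("reconstructed", spacing_mm = 0.25)
    cc <- phantom_config("contralateral", spacing_mm = 0.25)
    b <- make_case(cr, cc, interval_months = 12, seed = 200 + i)
    pr <- side_profiles(b)
    for (s in c("reconstructed", "contralateral")) {
      dens <- pr[[s]]$density_pct
      # non-increasing beyond the most superficial layer, within noise
      expect_true(all(diff(dens[2:8]) <= 1))
    }
    l1r[i] <- pr$reconstructed$density_pct[1]
    l1c[i] <- pr$contralateral$density_pct[1]
  }
  expect_true(all(l1r > l1c))
})

test_that("a contact-defect side propagates a QC exclusion", {
  cr <- phantom_config("reconstructed", spacing_mm = 0.5)
  cc <- phantom_config("contralateral", spacing_mm = 0.5,
                       contact_defect = list(gap_mm = 3, fraction = 0.2))
  b <- make_case(cr, cc, interval_months = 6, seed = 77)
  err <- tryCatch(side_profiles(b), pavasc_qc_exclusion = function(e) e)
  expect_s3_class(err, "pavasc_qc_exclusion")
  expect_match(conditionMessage(err), "contralateral")
})
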