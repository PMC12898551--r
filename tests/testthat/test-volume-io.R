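test_that("TIFF round trip is lossless with sidecar spacing", {
  set.seed(1)
  a <- array(sample(0:255, 16^3, replace = TRUE), c(16, 16, 16))
  storage.mode(a) <- "integer"
  vol <- pa_volume(a, 0.125)
  path <- file.path(tempdir(), "rt.tiff")
  save_volume(vol, path)
  back <- load_volume(path)
  expect_identical(back$data, vol$data)
  expect_equal(back$spacing, c(0.125, 0.125, 0.125))
  expect_true(is.integer(back$data))
  # page count equals the z dimension
  expect_length(tiff::readTIFF(path, all = TRUE), 16)
  # overwrite replaces content
  vol2 <- pa_volume(array(0L, c(4, 4, 2)), 0.5)
  save_volume(vol2, path)
  expect_identical(load_volume(path)$data, vol2$data)
})

test_that("NIfTI round trip preserves float data and spacing", {
  set.seed(2)
  a <- array(runif(10 * 12 * 8), c(10, 12, 8))
  vol <- pa_volume(a, c(0.125, 0.125, 0.25))
  path <- file.path(tempdir(), "rt.nii.gz")
  save_volume(vol, path)
  back <- load_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$spacing, c(0.125, 0.125, 0.25))
})

test_that("missing spacing is a hard error, never an assumption", {
  a <- array(0L, c(4, 4, 4))
  path <- file.path(tempdir(), "nospc.tiff")
  save_volume(pa_volume(a, 1), path)
  unlink(paste0(path, ".yaml"))
  expect_error(load_volume(path), "spacing")
  # explicit override works
  expect_equal(load_volume(path, spacing = 0.2)$spacing, rep(0.2, 3))
})

test_that("float data is rejected by the TIFF writer", {
  vol <- pa_volume(array(runif(8), c(2, 2, 2)), 1)
  expect_error(save_volume(vol, file.path(tempdir(), "f.tiff")), "8-bit")
})

test_that("case tables are typed and validated", {
  p <- file.path(tempdir(), "cases.csv")
  writeLines(c("case,interval_months", "1,26", "2,8", "3,18", "4,3",
               "5,12", "6,10", "7,30", "8,30"), p)
  df <- load_case_table(p)
  expect_equal(nrow(df), 8)
  expect_true(is.integer(df$interval_months))
  expect_equal(df$interval_months, c(26L, 8L, 18L, 3L, 12L, 10L, 30L, 30L))

  writeLines("case,interval_months", p)
  expect_equal(nrow(load_case_table(p)), 0)

  writeLines(c("case,interval_months", "1,26", "2,abc"), p)
  expect_error(load_case_table(p), "row.*2")

  writeLines(c("case,months", "1,26"), p)
  expect_error(load_case_table(p), "interval_months")
})

test_that("the packaged cohort table matches the study demographics", {
  df <- cohort_demographics()
  expect_equal(nrow(df), 8)
  expect_equal(df$interval_months, c(26L, 8L, 18L, 3L, 12L, 10L, 30L, 30L))
  expect_true(all(c("age_years", "bmi", "sessions") %in% names(df)))
})
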