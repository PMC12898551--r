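test_that("quadrants partition the en-face plane exactly", {
  ext <- c(80, 80, 20)
  for (centre in list(c(40, 40), c(33, 47))) {
    mk <- marking_set(ext, nipple_xy = centre)
    q <- divide_quadrants(mk, ext)
    areas <- vapply(q, function(r) diff(r$x_mm) * diff(r$y_mm), numeric(1))
    expect_equal(sum(areas), 80 * 80)
    # no overlap: x-ranges on each side of the centre split cleanly
    for (a in q) for (b in q) {
      if (identical(a$label, b$label)) next
      ox <- min(a$x_mm[2], b$x_mm[2]) - max(a$x_mm[1], b$x_mm[1])
      oy <- min(a$y_mm[2], b$y_mm[2]) - max(a$y_mm[1], b$y_mm[1])
      expect_lte(min(ox, oy), 0)
    }
  }
  mk_out <- marking_set(ext, nipple_xy = c(90, 40))
  expect_error(divide_quadrants(mk_out, ext), "outside")
})

test_that("ROI inner corners sit on the quadrant diagonal past the areola", {
  ext <- c(95, 95, 20)
  mk <- marking_set(ext, areola_radius_mm = 20)
  rois <- select_rois(mk, divide_quadrants(mk, ext), margin_mm = 2)
  expect_length(rois, 4)
  for (r in rois) {
    corner <- c(r$x_mm[which.min(abs(r$x_mm - 47.5))],
                r$y_mm[which.min(abs(r$y_mm - 47.5))])
    expect_equal(sqrt(sum((corner - c(47.5, 47.5))^2)), 22)
    expect_equal(diff(r$x_mm), 30)
    expect_equal(diff(r$y_mm), 30)
  }
  # pairwise disjoint
  labs <- names(rois)
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i >= j) next
    a <- rois[[i]]; b <- rois[[j]]
    ox <- min(a$x_mm[2], b$x_mm[2]) - max(a$x_mm[1], b$x_mm[1])
    oy <- min(a$y_mm[2], b$y_mm[2]) - max(a$y_mm[1], b$y_mm[1])
    expect_lt(min(ox, oy), 0)
  }
  # no marking position inside any ROI
  for (r in rois) {
    inside <- mk$marks$x_mm > r$x_mm[1] & mk$marks$x_mm < r$x_mm[2] &
      mk$marks$y_mm > r$y_mm[1] & mk$marks$y_mm < r$y_mm[2]
    expect_false(any(inside))
  }
})

test_that("ROIs that cannot fit raise a placement error", {
  ext <- c(60, 60, 20)
  mk <- marking_set(ext, areola_radius_mm = 12)
  expect_error(select_rois(mk, divide_quadrants(mk, ext)), "placement")
})

test_that("ROI extraction preserves values, spacing and depth", {
  ext <- c(80, 80, 20)
  s <- 0.5
  d <- round(ext / s)
  a <- array(seq_len(prod(d)) %% 251L, d)
  storage.mode(a) <- "integer"
  vol <- pa_volume(a, s)
  mk <- marking_set(ext)
  rois <- select_rois(mk, divide_quadrants(mk, ext))
  sub <- extract_roi(vol, rois[[1]])
  expect_equal(dim(sub$data)[1:2], c(60, 60)) # 30 mm at 0.5 mm
  expect_equal(dim(sub$data)[3], d[3])        # full depth
  expect_equal(sub$spacing, vol$spacing)
  ix <- attr(sub, "roi_index")
  expect_identical(sub$data[3, 5, 7],
                   vol$data[ix$x[1] + 2L, ix$y[1] + 4L, 7])
  # 0.125 mm spacing gives the canonical 240 x 240 en-face grid
  vol2 <- pa_volume(array(0L, c(640, 640, 4)), 0.125)
  sub2 <- extract_roi(vol2, rois[[1]])
  expect_equal(dim(sub2$data)[1:2], c(240, 240))
})

test_that("surface detection finds a flat skin plane with full contact", {
  a <- array(28L, c(30, 30, 20))
  vol <- pa_volume(a, 0.5)
  surf <- detect_surface(vol)
  expect_true(all(surf$offset_mm <= 0.5))
  expect_equal(surf$contact_fraction, 1)
})

test_that("an empty volume has no detectable surface anywhere", {
  vol <- pa_volume(array(0L, c(20, 20, 10)), 0.5)
  surf <- detect_surface(vol)
  expect_true(all(is.na(surf$offset_mm)))
  expect_equal(surf$contact_fraction, 0)
})

test_that("a 3 mm gap over 20% of the area breaks contact there", {
  cfg <- phantom_config("contralateral", extent_mm = c(40, 40, 20),
                        spacing_mm = 0.5, coverage = 0.15,
                        contact_defect = list(gap_mm = 3, fraction = 0.2))
  tree <- generate_vessel_tree(cfg, seed = 13)
  set.seed(13)
  vol <- render_volume(tree, cfg)
  surf <- detect_surface(vol)
  expect_lte(surf$contact_fraction, 0.8 + 0.02)
  expect_gte(surf$contact_fraction, 0.8 - 0.05)
  # the defect columns report the gap depth
  expect_true(median(surf$offset_mm[1:10, ], na.rm = TRUE) >= 2.5)
})

test_that("contact QC uses inclusive >= semantics at the threshold", {
  sm <- function(f) structure(list(contact_fraction = f), class = "surface_map")
  expect_equal(assess_contact(sm(1.0), 0.9)$verdict, "pass")
  expect_equal(assess_contact(sm(0.8), 0.9)$verdict, "exclude")
  expect_equal(assess_contact(sm(0.9), 0.9)$verdict, "pass")
})
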