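# 3x3 box mean with edge replication (en-face smoothing for surface detection)
box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (dx in -1:1) {
    xs <- pmin(pmax(seq_len(nr) + dx, 1L), nr)
    for (dy in -1:1) {
      ys <- pmin(pmax(seq_len(nc) + dy, 1L), nc)
      acc <- acc + m[xs, ys]
    }
  }
  acc / 9
}

# 3x3 median filter for small non-negative values; NA treated as "no surface"
med3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  X <- matrix(Inf, nr * nc, 9)
  k <- 0
  for (dx in -1:1) {
    xs <- pmin(pmax(seq_len(nr) + dx, 1L), nr)
    for (dy in -1:1) {
      ys <- pmin(pmax(seq_len(nc) + dy, 1L), nc)
      k <- k + 1
      X[, k] <- as.vector(m[xs, ys])
    }
  }
  X[is.na(X)] <- Inf
  vals <- sort(unique(X[is.finite(X)]))
  out <- rep(Inf, nr * nc)
  todo <- rep(TRUE, nr * nc)
  for (v in vals) {
    if (!any(todo)) break
    hit <- todo & rowSums(X <= v) >= 5
    out[hit] <- v
    todo <- todo & !hit
  }
  out[!is.finite(out)] <- NA_real_
  matrix(out, nr, nc)
}

#' Detect the skin surface and probe contact
#'
#' For each en-face column, the surface offset is the depth of the first voxel
#' whose 3 x 3 smoothed intensity exceeds the surface threshold; the offset
#' map is then 3 x 3 median-filtered. Columns where no voxel reaches the
#' threshold have no surface (offset `NA`) and count as non-contact. A column
#' is in contact when its offset is at most `tolerance_mm`.
#'
#' All downstream depth computations reference this per-column surface, not
#' the nominal z = 0 plane: that correction is exactly what insufficient
#' probe–skin contact makes impossible, hence the contact QC.
#'
#' @param vol A [pa_volume()].
#' @param threshold Surface intensity threshold (0–255 scale).
#' @param tolerance_mm Contact tolerance (mm).
#' @return An object of class `surface_map`: `offset_mm` matrix, logical
#'   `contact` matrix, `contact_fraction`, and parameters.
#' @export
detect_surface <- function(vol, threshold = 20, tolerance_mm = 0.5) {
  stopifnot(inherits(vol, "pa_volume"))
  if (threshold < 0 || threshold > 255) stop("surface threshold must be in [0, 255]")
  d <- dim(vol$data)
  dz <- vol$spacing[3]
  off <- matrix(NA_real_, d[1], d[2]) # voxel index (0-based) of first exceedance
  todo <- matrix(TRUE, d[1], d[2])
  for (k in seq_len(d[3])) {
    if (!any(todo)) break
    sm <- box3(vol$data[, , k])
    hit <- todo & sm > threshold
    off[hit] <- k - 1
    todo <- todo & !hit
  }
  off <- med3x3(off)
  off_mm <- off * dz
  contact <- !is.na(off_mm) & off_mm <= tolerance_mm
  structure(list(offset_mm = off_mm, contact = contact,
                 contact_fraction = mean(contact),
                 threshold = threshold, tolerance_mm = tolerance_mm,
                 spacing = vol$spacing),
            class = "surface_map")
}

#' Probe-contact quality control verdict
#'
#' A side is excluded from depth-referenced analysis when its contact fraction
#' falls below `min_fraction` (boundary inclusive: exactly `min_fraction`
#' passes). Mirrors the study design in which cases with insufficient
#' device–skin contact were excluded from the vascular density analysis.
#'
#' @param surface A [detect_surface()] result.
#' @param min_fraction Minimum acceptable contact fraction.
#' @return An object of class `qc_verdict` with `verdict` (`"pass"` /
#'   `"exclude"`) and the measured fraction.
#' @export
assess_contact <- function(surface, min_fraction = 0.9) {
  stopifnot(inherits(surface, "surface_map"))
  structure(list(verdict = if (surface$contact_fraction >= min_fraction) "pass" else "exclude",
                 contact_fraction = surface$contact_fraction,
                 min_fraction = min_fraction),
            class = "qc_verdict")
}

#' Divide the en-face plane into four quadrants
#'
#' Axis-aligned partition at the nipple centre's x and y, labelled
#' upper/lower (y above/below the centre) and medial/lateral (x below/above).
#' The four half-open regions tile the plane with no overlap and no gap.
#'
#' @param markings A [marking_set()].
#' @param extent_mm En-face extent (x, y) in mm.
#' @return Named list of 4 regions with `x_mm` / `y_mm` half-open ranges.
#' @export
divide_quadrants <- function(markings, extent_mm) {
  stopifnot(inherits(markings, "marking_set"))
  c0 <- markings$nipple_xy
  ex <- extent_mm[1:2]
  if (any(c0 <= 0) || any(c0 >= ex))
    stop("nipple centre lies outside the en-face extent")
  q <- list(
    `upper-medial`  = list(x_mm = c(0, c0[1]),     y_mm = c(c0[2], ex[2])),
    `upper-lateral` = list(x_mm = c(c0[1], ex[1]), y_mm = c(c0[2], ex[2])),
    `lower-medial`  = list(x_mm = c(0, c0[1]),     y_mm = c(0, c0[2])),
    `lower-lateral` = list(x_mm = c(c0[1], ex[1]), y_mm = c(0, c0[2]))
  )
  for (nm in names(q)) q[[nm]]$label <- nm
  q
}

#' Place one 30 x 30 mm ROI per quadrant
#'
#' Each ROI's inner corner sits on the quadrant diagonal at Euclidean distance
#' `areola_radius + margin` from the nipple centre, and the square extends
#' away from the centre. By construction the ROI excludes the areola disc
#' (closest point is the inner corner) and all axis-aligned marking positions
#' (the square never touches the quadrant axes); both exclusions are also
#' verified numerically.
#'
#' @param markings A [marking_set()].
#' @param quadrants A [divide_quadrants()] result.
#' @param margin_mm Offset beyond the areola border (mm).
#' @param size_mm ROI side length (mm).
#' @return List of 4 `roi_spec` objects (`label`, `x_mm`, `y_mm` ranges).
#' @export
select_rois <- function(markings, quadrants, margin_mm = 2, size_mm = 30) {
  stopifnot(inherits(markings, "marking_set"))
  c0 <- markings$nipple_xy
  r <- markings$areola_radius_mm
  inner <- (r + margin_mm) / sqrt(2)
  out <- list()
  for (q in quadrants) {
    sx <- if (mean(q$x_mm) >= c0[1]) 1 else -1
    sy <- if (mean(q$y_mm) >= c0[2]) 1 else -1
    corner <- c0 + inner * c(sx, sy)
    xr <- sort(c(corner[1], corner[1] + sx * size_mm))
    yr <- sort(c(corner[2], corner[2] + sy * size_mm))
    if (xr[1] < min(q$x_mm) - 1e-9 || xr[2] > max(q$x_mm) + 1e-9 ||
        yr[1] < min(q$y_mm) - 1e-9 || yr[2] > max(q$y_mm) + 1e-9)
      stop("ROI placement error: a ", size_mm, " mm ROI at areola radius ", r,
           " + ", margin_mm, " mm margin does not fit inside quadrant ", q$label)
    # nearest point of the rectangle to the nipple centre must clear the areola
    nearest <- pmin(pmax(c0, c(xr[1], yr[1])), c(xr[2], yr[2]))
    if (sqrt(sum((nearest - c0)^2)) < r - 1e-9)
      stop("ROI placement error: rectangle intersects the areola disc")
    inside <- markings$marks$x_mm > xr[1] & markings$marks$x_mm < xr[2] &
      markings$marks$y_mm > yr[1] & markings$marks$y_mm < yr[2]
    if (any(inside))
      stop("ROI placement error: rectangle contains marking positions")
    out[[q$label]] <- structure(list(label = q$label, x_mm = xr, y_mm = yr,
                                     size_mm = size_mm),
                                class = "roi_spec")
  }
  out
}

#' Extract the sub-volume under an ROI
#'
#' Returns the full-depth sub-volume under the en-face rectangle, with
#' spacing preserved and the ROI origin recorded (so surface offsets can be
#' aligned to the parent volume).
#'
#' @param vol A [pa_volume()].
#' @param spec A `roi_spec` from [select_rois()].
#' @return A [pa_volume()] with attributes `roi_origin_mm` and `roi_index`
#'   (1-based en-face index ranges into the parent grid).
#' @export
extract_roi <- function(vol, spec) {
  stopifnot(inherits(vol, "pa_volume"), inherits(spec, "roi_spec"))
  s <- vol$spacing
  d <- dim(vol$data)
  i0 <- as.integer(round(spec$x_mm[1] / s[1]))
  j0 <- as.integer(round(spec$y_mm[1] / s[2]))
  ni <- as.integer(round(spec$size_mm / s[1]))
  nj <- as.integer(round(spec$size_mm / s[2]))
  if (i0 < 0 || j0 < 0 || i0 + ni > d[1] || j0 + nj > d[2])
    stop("ROI exceeds the volume extent")
  sub <- vol$data[(i0 + 1):(i0 + ni), (j0 + 1):(j0 + nj), , drop = FALSE]
  out <- pa_volume(sub, s)
  attr(out, "roi_origin_mm") <- c(i0 * s[1], j0 * s[2])
  attr(out, "roi_index") <- list(x = c(i0 + 1L, i0 + ni), y = c(j0 + 1L, j0 + nj))
  attr(out, "roi_label") <- spec$label
  out
}

# surface offsets restricted to an extracted ROI's columns
crop_surface_to_roi <- function(surface, roi) {
  ix <- attr(roi, "roi_index")
  if (is.null(ix)) stop("roi lacks index metadata; use extract_roi()")
  surface$offset_mm[ix$x[1]:ix$x[2], ix$y[1]:ix$y[2], drop = FALSE]
}
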