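#' Measure vessel diameters in a binarised ROI
#'
#' Automated surrogate for manual caliper measurements on clearly visible,
#' relatively straight vessel segments: (i) the mask is skeletonised to
#' 1-voxel centrelines by distance-ordered homotopic thinning; (ii) branch
#' points (skeleton voxels with 3+ skeleton neighbours) are detected; (iii)
#' skeleton voxels within `excl_factor` x local diameter of any branch point
#' are excluded, avoiding the widened bifurcation region; (iv) only straight
#' windows are retained (`window`-voxel centreline windows whose maximum
#' perpendicular deviation from the chord is at most `chord_tol` voxels);
#' (v) the diameter at a voxel is twice its Euclidean distance-transform
#' value times the voxel spacing; (vi) one measurement is taken per connected
#' straight run, at the window of minimal deviation; (vii) diameters outside
#' the measurable range are discarded.
#'
#' @param mask A binarised [pa_volume()] (logical data, isotropic spacing).
#' @param window Straightness window length in voxels (odd).
#' @param chord_tol Maximum chord deviation in voxels.
#' @param excl_factor Branch exclusion radius as a multiple of the local
#'   diameter.
#' @param range_mm Measurable diameter range; measurements outside are
#'   dropped.
#' @return A data.frame with one row per measurement: `x_mm, y_mm, z_mm,
#'   diameter_mm, deviation_vox`. Empty mask gives zero rows.
#' @export
measure_diameters <- function(mask, window = 11, chord_tol = 1.0,
                              excl_factor = 2.0, range_mm = c(0.08, 1.3)) {
  stopifnot(inherits(mask, "pa_volume"), is.logical(mask$data))
  sp <- mask$spacing
  if (max(sp) - min(sp) > 1e-9)
    stop("unsupported input: diameter measurement requires isotropic spacing")
  s <- sp[1]
  if (window < 3 || window %% 2 != 1) stop("window must be an odd count >= 3")
  empty <- data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      diameter_mm = numeric(0), deviation_vox = numeric(0))
  m <- mask$data
  if (!any(m)) return(empty)

  # crop to the foreground bounding box (plus margin) to bound the EDT and
  # thinning cost; results are mapped back to parent coordinates
  pos <- which(m, arr.ind = TRUE)
  pad <- 4L
  d <- dim(m)
  lo <- pmax(apply(pos, 2, min) - pad, 1L)
  hi <- pmin(apply(pos, 2, max) + pad, d)
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dims <- dim(sub)

  # distances are only needed inside tubes, whose radius is bounded by the
  # measurable range; the capped transform is exact up to that bound
  cap <- ceiling(range_mm[2] / 2 / s) + 2
  edt <- cpp_edt_capped(as.vector(sub), dims, cap)
  skel <- cpp_thin(as.vector(sub), edt, dims)
  res <- cpp_measure_skeleton(as.vector(skel), edt, dims,
                              half = (window - 1L) %/% 2L,
                              chord_tol = chord_tol, excl_factor = excl_factor)
  if (!nrow(res)) return(empty)
  df <- data.frame(
    x_mm = (res[, "x"] + lo[1] - 1 - 0.5) * s,
    y_mm = (res[, "y"] + lo[2] - 1 - 0.5) * s,
    z_mm = (res[, "z"] + lo[3] - 1 - 0.5) * s,
    diameter_mm = res[, "diameter_vox"] * s,
    deviation_vox = res[, "deviation_vox"])
  df[df$diameter_mm >= range_mm[1] & df$diameter_mm <= range_mm[2], , drop = FALSE]
}

#' Derive caliber classification cutoffs from pooled contralateral diameters
#'
#' Quartiles are computed by linear interpolation between order statistics at
#' positions `(n - 1) p + 1` and the first/third quartiles are rounded half-up
#' to the nearest 0.1 mm to give the lower/upper classification cutoffs
#' (reproducing 0.29 -> 0.3 and 0.50 -> 0.5 mm).
#'
#' @param diameters Pooled diameters (mm), n >= 4, not all equal.
#' @return An object of class `cutoff_set`: `q1, median, q3, lower, upper, n`.
#' @export
derive_cutoffs <- function(diameters) {
  diameters <- diameters[!is.na(diameters)]
  n <- length(diameters)
  if (n < 4) stop("at least 4 diameter measurements are required")
  if (max(diameters) == min(diameters))
    stop("degenerate sample: all diameters equal")
  q <- quantile(diameters, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lower <- round_half_up(q[1], 1)
  upper <- round_half_up(q[3], 1)
  if (lower >= upper)
    stop("degenerate cutoffs: rounded quartiles collapse (", lower, " mm)")
  structure(list(q1 = q[1], median = q[2], q3 = q[3],
                 lower = lower, upper = upper, n = n),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("<cutoff_set> quartiles %.3f / %.3f / %.3f mm (n = %d) -> cutoffs %.1f / %.1f mm\n",
              x$q1, x$median, x$q3, x$n, x$lower, x$upper))
  invisible(x)
}

#' Classify vessel diameters into small / medium / large
#'
#' Boundary-inclusive to medium: a diameter exactly at a cutoff is medium.
#' Diameters outside the measurable range (0.08–1.3 mm) are an error.
#'
#' @param diameter_mm Diameters (mm).
#' @param cutoffs A [derive_cutoffs()] result.
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
classify_diameter <- function(diameter_mm, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  if (any(diameter_mm < 0.08 - 1e-12 | diameter_mm > 1.3 + 1e-12))
    stop("diameter outside the measurable range [0.08, 1.3] mm")
  cls <- ifelse(diameter_mm < cutoffs$lower, "small",
                ifelse(diameter_mm > cutoffs$upper, "large", "medium"))
  factor(cls, levels = c("small", "medium", "large"))
}

#' Caliber class proportions
#'
#' Class counts divided by the number of measurements, per (case, side) group
#' when the sample carries those columns, otherwise for the pooled sample.
#'
#' @param samples A data.frame with a `diameter_mm` column (and optionally
#'   `case`, `side`).
#' @param cutoffs A [derive_cutoffs()] result.
#' @return A data.frame with columns `case`, `side`, `small`, `medium`,
#'   `large`, `n`; the fractions sum to 1 per row.
#' @export
caliber_proportions <- function(samples, cutoffs) {
  if (!nrow(samples)) stop("no diameter measurements supplied")
  if (!"case" %in% names(samples)) samples$case <- "all"
  if (!"side" %in% names(samples)) samples$side <- "all"
  cls <- classify_diameter(samples$diameter_mm, cutoffs)
  groups <- split(seq_len(nrow(samples)),
                  list(case = samples$case, side = samples$side), drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    ix <- groups[[g]]
    tab <- table(cls[ix])
    data.frame(case = samples$case[ix[1]], side = samples$side[ix[1]],
               small = as.numeric(tab["small"]) / length(ix),
               medium = as.numeric(tab["medium"]) / length(ix),
               large = as.numeric(tab["large"]) / length(ix),
               n = length(ix))
  }))
  rownames(out) <- NULL
  out[order(out$case, out$side), , drop = FALSE]
}

#' Measure all ROIs of one rendered side
#'
#' Convenience wrapper running ROI selection, extraction, grayscale,
#' binarisation and [measure_diameters()] over the four periareolar ROIs of
#' one side, tagging each measurement with its quadrant.
#'
#' @param vol Rendered side volume ([pa_volume()]).
#' @param markings The case [marking_set()].
#' @param threshold Binarisation threshold.
#' @param zmax_mm Optional depth limit (mm): voxels deeper than this are
#'   dropped before measuring (used to restrict measurement to the optically
#'   resolvable depth range).
#' @param ... Passed to [measure_diameters()].
#' @return A data.frame of measurements with a `quadrant` column.
#' @export
measure_side <- function(vol, markings, threshold = 75, zmax_mm = NULL, ...) {
  quads <- divide_quadrants(markings, dim(vol$data)[1:2] * vol$spacing[1:2])
  specs <- select_rois(markings, quads)
  out <- lapply(specs, function(sp) {
    roi <- binarize(to_grayscale(extract_roi(vol, sp)), threshold)
    if (!is.null(zmax_mm)) {
      org <- attr(roi, "roi_origin_mm")
      kmax <- min(dim(roi$data)[3], max(1L, floor(zmax_mm / roi$spacing[3])))
      roi <- pa_volume(roi$data[, , seq_len(kmax), drop = FALSE], roi$spacing)
      attr(roi, "roi_origin_mm") <- org
    }
    df <- measure_diameters(roi, ...)
    if (nrow(df)) {
      org <- attr(roi, "roi_origin_mm")
      df$x_mm <- df$x_mm + org[1]
      df$y_mm <- df$y_mm + org[2]
      df$quadrant <- sp$label
    }
    df
  })
  out <- out[vapply(out, nrow, 1L) > 0]
  if (!length(out))
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      diameter_mm = numeric(0), deviation_vox = numeric(0),
                      quadrant = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
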