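#' The eight-layer depth scheme
#'
#' Eight contiguous half-open 2.5 mm depth intervals covering \[0, 20) mm
#' from the detected skin surface.
#'
#' @return A data.frame with columns `layer`, `lo_mm`, `hi_mm`.
#' @export
depth_layers <- function() {
  data.frame(layer = 1:8, lo_mm = seq(0, 17.5, by = 2.5),
             hi_mm = seq(2.5, 20, by = 2.5))
}

#' Assign corrected depths to layers
#'
#' Half-open convention: a depth exactly on a boundary belongs to the deeper
#' layer (2.5 mm is in layer 2, \[2.5, 5)). Depths outside \[0, 20) return `NA`.
#'
#' @param depth_mm Numeric depths from the detected surface (mm).
#' @param scheme A [depth_layers()] scheme.
#' @return Integer layer indices (1–8) or `NA`.
#' @export
assign_depth_layer <- function(depth_mm, scheme = depth_layers()) {
  w <- scheme$hi_mm[1] - scheme$lo_mm[1]
  lay <- floor(depth_mm / w) + 1
  lay[depth_mm < scheme$lo_mm[1] | depth_mm >= max(scheme$hi_mm)] <- NA
  as.integer(lay)
}

#' Convert a volume to 8-bit grayscale
#'
#' A volume that is already 8-bit (integers within \[0, 255\]) passes through
#' unchanged, so the fixed binarisation threshold keeps its absolute meaning.
#' Any other numeric data is mapped linearly from its min–max range onto
#' \[0, 255\] and rounded half-up; a constant volume maps to all zeros.
#'
#' @param vol A [pa_volume()] with any numeric dtype.
#' @return A [pa_volume()] with integer data in \[0, 255\].
#' @export
to_grayscale <- function(vol) {
  stopifnot(inherits(vol, "pa_volume"))
  a <- vol$data
  lo <- min(a); hi <- max(a)
  if (hi == lo) {
    a[] <- 0L
    storage.mode(a) <- "integer"
  } else if (is.integer(a) && lo >= 0L && hi <= 255L) {
    # already 8-bit: identity
  } else {
    a <- floor((a - lo) / (hi - lo) * 255 + 0.5)
    storage.mode(a) <- "integer"
  }
  out <- pa_volume(a, vol$spacing)
  for (at in c("roi_origin_mm", "roi_index", "roi_label"))
    attr(out, at) <- attr(vol, at)
  out
}

#' Binarise an 8-bit volume
#'
#' Foreground where the voxel value is strictly above the threshold ("pixels
#' above the threshold"); a voxel exactly at the threshold is background.
#'
#' @param vol An 8-bit [pa_volume()] (from [to_grayscale()]).
#' @param threshold Integer threshold in \[0, 255\]; default 75.
#' @return A [pa_volume()] with logical data.
#' @export
binarize <- function(vol, threshold = 75) {
  stopifnot(inherits(vol, "pa_volume"))
  if (threshold < 0 || threshold > 255)
    stop("binarisation threshold must be in [0, 255]")
  a <- vol$data
  if (min(a) < 0 || max(a) > 255)
    stop("binarize expects an 8-bit volume; run to_grayscale() first")
  m <- a > threshold
  out <- pa_volume(m, vol$spacing)
  for (at in c("roi_origin_mm", "roi_index", "roi_label"))
    attr(out, at) <- attr(vol, at)
  attr(out, "threshold") <- threshold
  out
}

#' Depth-stratified vascular density
#'
#' Pools one or more binarised ROI sub-volumes into an eight-layer density
#' profile. Each voxel's depth is corrected by the surface offset of its
#' en-face column and assigned to a layer by the half-open scheme; voxels
#' with corrected depth outside \[0, 20) mm (or in columns without a detected
#' surface) are ignored.
#'
#' Two counting conventions are available. `"projection"` (default) computes,
#' per layer, the fraction of en-face pixels whose column contains at least
#' one foreground voxel within the layer — the density of the binarised 2D
#' layer image. `"voxel"` counts foreground over all 3D voxels in the layer.
#' Counts are pooled over all supplied ROIs (single ratio, not a per-ROI
#' average).
#'
#' @param rois List of binarised ROI volumes ([binarize()] output).
#' @param surfaces List of per-ROI surface offset matrices (mm), matching each
#'   ROI's en-face grid, or `NULL` for a flat surface at z = 0.
#' @param scheme A [depth_layers()] scheme.
#' @param method `"projection"` or `"voxel"`.
#' @return An object of class `depth_profile`: `density_pct` (8 values),
#'   layer scheme, method, pooled counts and ROI count.
#' @export
density_profile <- function(rois, surfaces = NULL, scheme = depth_layers(),
                            method = c("projection", "voxel")) {
  method <- match.arg(method)
  if (!length(rois)) stop("at least one ROI is required")
  if (!is.null(surfaces) && length(surfaces) != length(rois))
    stop("one surface offset matrix per ROI is required")
  nlay <- nrow(scheme)
  fg <- numeric(nlay); tot <- numeric(nlay)
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    stopifnot(inherits(roi, "pa_volume"), is.logical(roi$data))
    d <- dim(roi$data)
    dz <- roi$spacing[3]
    ncell <- d[1] * d[2]
    off <- if (is.null(surfaces)) numeric(ncell) else as.vector(surfaces[[i]])
    if (length(off) != ncell) stop("surface offsets do not match ROI en-face grid")
    if (method == "projection") {
      pfg <- matrix(FALSE, ncell, nlay)
      ptot <- matrix(FALSE, ncell, nlay)
    }
    for (k in seq_len(d[3])) {
      zk <- (k - 0.5) * dz
      lay <- assign_depth_layer(zk - off, scheme)
      valid <- which(!is.na(lay))
      if (!length(valid)) next
      lv <- lay[valid]
      mk <- as.vector(roi$data[, , k])[valid]
      if (method == "voxel") {
        tot <- tot + tabulate(lv, nlay)
        if (any(mk)) fg <- fg + tabulate(lv[mk], nlay)
      } else {
        ptot[cbind(valid, lv)] <- TRUE
        sel <- valid[mk]
        if (length(sel)) pfg[cbind(sel, lay[sel])] <- TRUE
      }
    }
    if (method == "projection") {
      tot <- tot + colSums(ptot)
      fg <- fg + colSums(pfg)
    }
  }
  if (any(tot == 0))
    stop("undefined density: layer(s) ", paste(which(tot == 0), collapse = ", "),
         " contain no voxels")
  structure(list(density_pct = 100 * fg / tot, scheme = scheme,
                 method = method, foreground = fg, total = tot,
                 n_rois = length(rois)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s counting, %d ROI(s)\n", x$method, x$n_rois))
  print(data.frame(layer_mm = sprintf("%.1f-%.1f", x$scheme$lo_mm, x$scheme$hi_mm),
                   density_pct = round(x$density_pct, 2)), row.names = FALSE)
  invisible(x)
}

qc_exclusion <- function(sides, qc, min_fraction) {
  fr <- vapply(sides, function(s) qc[[s]]$contact_fraction, numeric(1))
  stop(errorCondition(
    sprintf("side(s) %s excluded by contact QC (contact fraction %s < %.2f)",
            paste(sides, collapse = ", "),
            paste(sprintf("%.3f", fr), collapse = ", "), min_fraction),
    class = "pavasc_qc_exclusion", sides = sides, qc = qc))
}

#' Depth profiles for both sides of a case
#'
#' Runs the full density pipeline per side: surface detection, contact QC
#' (raising a QC-exclusion error when a side fails), quadrant division, ROI
#' selection and extraction, grayscale conversion, binarisation, and pooled
#' depth-stratified density.
#'
#' @param bundle A [make_case()] bundle with rendered volumes.
#' @param threshold Binarisation threshold.
#' @param surface_threshold,tolerance_mm Surface detection parameters.
#' @param min_contact Minimum contact fraction for QC.
#' @param method Density counting convention (see [density_profile()]).
#' @return List with `reconstructed` and `contralateral` depth profiles and
#'   the per-side QC verdicts.
#' @export
side_profiles <- function(bundle, threshold = 75, surface_threshold = 20,
                          tolerance_mm = 0.5, min_contact = 0.9,
                          method = c("projection", "voxel")) {
  stopifnot(inherits(bundle, "case_bundle"))
  method <- match.arg(method)
  quads <- divide_quadrants(bundle$markings, bundle$reconstructed$config$extent_mm)
  specs <- select_rois(bundle$markings, quads)
  sides <- c("reconstructed", "contralateral")
  surf <- list()
  qc <- list()
  for (s in sides) {
    vol <- bundle[[s]]$volume
    if (is.null(vol)) stop("case bundle has no rendered volume for side ", s)
    surf[[s]] <- detect_surface(vol, threshold = surface_threshold,
                                tolerance_mm = tolerance_mm)
    qc[[s]] <- assess_contact(surf[[s]], min_contact)
  }
  bad <- sides[vapply(sides, function(s) qc[[s]]$verdict == "exclude", logical(1))]
  if (length(bad)) qc_exclusion(bad, qc, min_contact)
  out <- list(qc = qc)
  for (s in sides) {
    vol <- bundle[[s]]$volume
    rois <- lapply(specs, function(sp) binarize(to_grayscale(extract_roi(vol, sp)),
                                                threshold))
    offs <- lapply(rois, function(r) crop_surface_to_roi(surf[[s]], r))
    prof <- density_profile(rois, offs, method = method)
    prof$side <- s
    prof$case_id <- bundle$case_id
    prof$threshold <- threshold
    out[[s]] <- prof
  }
  out
}
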