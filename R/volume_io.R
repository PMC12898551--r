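#' Intensity volume container
#'
#' A 3D scalar grid with explicit voxel spacing. Axis order is fixed across
#' the package: `[x, y, z]` with x lateral, y craniocaudal and z depth; z = 0
#' is the nominal skin plane and z increases into tissue. Indices are 0-based
#' in world-coordinate formulas and intervals are half-open; voxel `i`
#' (0-based) spans `[i*s, (i+1)*s)` mm and has centre `(i + 0.5) * s`.
#'
#' @param data Numeric or integer 3D array, dim = (nx, ny, nz).
#' @param spacing Voxel spacing in mm, length 3 (per axis) or 1 (isotropic).
#' @return An object of class `pa_volume`.
#' @export
pa_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3 || any(dim(data) < 1))
    stop("data must be a non-empty 3D array")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive, per axis, in mm")
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "pa_volume")
}

#' @export
print.pa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pa_volume> %d x %d x %d voxels, spacing %s mm, extent %s mm, %s\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, trim = TRUE), collapse = " x "),
              paste(format(d * x$spacing, trim = TRUE), collapse = " x "),
              storage.mode(x$data)))
  invisible(x)
}

#' @export
dim.pa_volume <- function(x) dim(x$data)

vol_extent <- function(vol) dim(vol$data) * vol$spacing

sidecar_path <- function(path) paste0(path, ".yaml")

guess_format <- function(path) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) return("tiff")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  stop("cannot infer volume format from path: ", path)
}

#' Save an intensity volume
#'
#' Two on-disk formats are supported: multi-page TIFF (8-bit volumes; one page
#' per z slice, voxel spacing in a YAML sidecar `<path>.yaml`) and NIfTI-1
#' (any numeric type; spacing carried in the header). A saved file reloads via
#' [load_volume()] with an identical grid and spacing.
#'
#' @param vol A [pa_volume()] object.
#' @param path Output path; the parent directory must exist.
#' @param format `"tiff"`, `"nifti"` or `"auto"` (from the file extension).
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path, format = c("auto", "tiff", "nifti")) {
  stopifnot(inherits(vol, "pa_volume"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  if (format == "tiff") {
    a <- vol$data
    if (min(a) < 0 || max(a) > 255 || any(a != floor(a)))
      stop("TIFF output supports 8-bit volumes (integers in [0, 255]); use NIfTI for float data")
    pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    yaml::write_yaml(list(spacing_mm = vol$spacing), sidecar_path(path))
  } else {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Load an intensity volume
#'
#' Voxel spacing must be present (NIfTI header or TIFF YAML sidecar) or
#' supplied through `spacing`; a missing spacing is a hard error, never a
#' silent assumption, because every depth computation downstream uses it.
#'
#' @param path File to read.
#' @param format `"tiff"`, `"nifti"` or `"auto"`.
#' @param spacing Optional explicit spacing override (mm).
#' @return A [pa_volume()].
#' @export
load_volume <- function(path, format = c("auto", "tiff", "nifti"), spacing = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    a <- array(0L, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) a[, , k] <- pages[[k]]
    storage.mode(a) <- "integer"
    if (is.null(spacing)) {
      sc <- sidecar_path(path)
      if (!file.exists(sc))
        stop("no voxel spacing: TIFF sidecar ", sc,
             " not found and no explicit spacing supplied")
      spacing <- unlist(yaml::read_yaml(sc)$spacing_mm)
      if (is.null(spacing)) stop("sidecar ", sc, " lacks spacing_mm")
    }
  } else {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) != 3) stop("expected a 3D NIfTI volume: ", path)
    if (is.null(spacing)) {
      spacing <- RNifti::pixdim(img)[1:3]
      if (any(!is.finite(spacing)) || any(spacing <= 0))
        stop("NIfTI header of ", path, " lacks a usable pixdim; supply spacing explicitly")
    }
  }
  pa_volume(a, spacing)
}

#' Load a per-case metadata table
#'
#' Reads a CSV with one row per imaging case. Required columns: `case`
#' (identifier) and `interval_months` (integer months from final surgery to
#' imaging). Any further columns (age, BMI, surgery type, ...) are passed
#' through unchanged.
#'
#' @param path CSV file path.
#' @return A data.frame with typed columns; zero rows for a header-only file.
#' @export
load_case_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("case", "interval_months")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("case table is missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    iv <- suppressWarnings(as.numeric(df$interval_months))
    bad <- which(is.na(iv) | iv != floor(iv))
    if (length(bad))
      stop("non-integer interval_months in row(s) ", paste(bad, collapse = ", "),
           " of ", path)
    if (any(iv < 0)) stop("interval_months must be >= 0")
    df$interval_months <- as.integer(iv)
  } else {
    df$interval_months <- integer(0)
  }
  df
}

#' Demographics of the eight-case imaging cohort
#'
#' The per-case demographics and treatment details of the imaging cohort the
#' pipeline's summary statistics are checked against: age, body-mass index,
#' surgery type, adjuvant therapy, ASC supplementation, number of grafting
#' sessions, and the interval from final surgery to imaging.
#'
#' @return A data.frame with 8 rows.
#' @export
cohort_demographics <- function() {
  load_case_table(system.file("extdata", "cohort_demographics.csv",
                              package = "pavasc", mustWork = TRUE))
}
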