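#' Phantom configuration
#'
#' Parameters of the synthetic paired-breast photoacoustic phantom. The
#' defaults are calibrated to the statistical structure the analysis assumes:
#' superficial (0–2.5 mm) binarised vascular coverage of 28.2% on the
#' reconstructed side and 19.8% on the contralateral side, vessel diameters
#' drawn from the quartile-anchored distribution (Q1/median/Q3 =
#' 0.29/0.37/0.50 mm on the contralateral side), single-exponential optical
#' attenuation with depth, and a remodeling shift of the reconstructed-side
#' diameter distribution toward smaller calibers with longer postoperative
#' interval.
#'
#' @param side `"reconstructed"` or `"contralateral"`.
#' @param extent_mm Volume extent (x, y, z) in mm. The en-face extent must
#'   accommodate four 30 x 30 mm periareolar ROIs around the areola disc.
#' @param spacing_mm Isotropic voxel spacing in mm. 0.125 mm resolves the
#'   smallest modelled vessel (0.08 mm, rendered as a single-voxel trace).
#' @param coverage Target binarised en-face coverage of the 0–2.5 mm layer
#'   (fraction). Defaults to 0.282 (reconstructed) / 0.198 (contralateral).
#' @param anchors Diameter distribution ([quantile_anchors()]).
#' @param interval_months Postoperative interval; shifts the reconstructed
#'   side's anchors via [shift_anchors()].
#' @param remodeling_rate Anchor shrinkage rate per month (reconstructed side
#'   only). The default 0.01/month reproduces small-vessel proportions near
#'   55–60% at 26–30 months.
#' @param mu_eff Effective optical attenuation coefficient (1/mm).
#' @param amplitude Vessel signal amplitude at the surface (8-bit scale).
#' @param bg_level,noise_sd Tissue background baseline and Gaussian noise sd
#'   (8-bit scale); the defaults keep the >75 false-foreground rate well
#'   below 1%.
#' @param depth_scale Mean of the (truncated-exponential) vessel seeding depth
#'   in mm; makes latent vessel density decay with depth.
#' @param contact_defect `NULL`, or `list(gap_mm =, fraction =)`: the skin
#'   surface is displaced into the volume by `gap_mm` over `fraction` of the
#'   en-face area, emulating insufficient probe–skin contact.
#' @param areola_radius_mm Areola disc radius used for the marking model.
#' @param length_budget_mm Total centerline length budget for tree growth.
#' @param seed Optional default seed carried by the config.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(side = c("contralateral", "reconstructed"),
                           extent_mm = c(80, 80, 20),
                           spacing_mm = 0.125,
                           coverage = NULL,
                           anchors = quantile_anchors(),
                           interval_months = 0,
                           remodeling_rate = 0.01,
                           mu_eff = 0.15,
                           amplitude = 240,
                           bg_level = 28,
                           noise_sd = 12,
                           depth_scale = 6,
                           contact_defect = NULL,
                           areola_radius_mm = 12,
                           length_budget_mm = 2e5,
                           seed = NULL) {
  side <- match.arg(side)
  if (is.null(coverage))
    coverage <- if (side == "reconstructed") 0.282 else 0.198
  stopifnot(length(extent_mm) == 3, all(extent_mm > 0))
  if (extent_mm[3] < 20) stop("depth extent must be >= 20 mm for density analysis")
  if (length(spacing_mm) != 1 || spacing_mm <= 0) stop("spacing must be a positive scalar (isotropic)")
  if (coverage < 0 || coverage > 1) stop("coverage must be a fraction in [0, 1]")
  if (mu_eff < 0) stop("mu_eff must be >= 0")
  if (interval_months < 0) stop("interval must be >= 0")
  if (!is.null(contact_defect)) {
    stopifnot(is.list(contact_defect),
              contact_defect$gap_mm > 0,
              contact_defect$fraction > 0, contact_defect$fraction <= 1)
  }
  structure(list(side = side, extent_mm = as.numeric(extent_mm),
                 spacing_mm = spacing_mm, coverage = coverage,
                 anchors = anchors, interval_months = interval_months,
                 remodeling_rate = remodeling_rate, mu_eff = mu_eff,
                 amplitude = amplitude, bg_level = bg_level,
                 noise_sd = noise_sd, depth_scale = depth_scale,
                 contact_defect = contact_defect,
                 areola_radius_mm = areola_radius_mm,
                 length_budget_mm = length_budget_mm, seed = seed),
            class = "phantom_config")
}

#' Effective diameter anchors of a phantom side
#'
#' Contralateral sides use the configured anchors unchanged; reconstructed
#' sides are shifted toward smaller calibers in proportion to
#' `interval_months * remodeling_rate`.
#'
#' @param config A [phantom_config()].
#' @return A `quantile_anchors` object.
#' @export
effective_anchors <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$side == "reconstructed" &&
      config$interval_months * config$remodeling_rate > 0)
    shift_anchors(config$anchors, config$interval_months, config$remodeling_rate)
  else
    config$anchors
}

#' Skin marking model
#'
#' Marks at 20 mm intervals along the four axis-aligned rays (cranial, caudal,
#' medial, lateral) through the nipple centre, plus the areola disc radius.
#' Marking coordinates are metadata: the analysis uses them to divide
#' quadrants and place ROIs, never to detect markings from image content.
#'
#' @param extent_mm En-face extent (x, y) in mm.
#' @param nipple_xy Nipple centre (mm); defaults to the extent midpoint.
#' @param areola_radius_mm Areola radius (mm).
#' @param mark_interval_mm Spacing between consecutive marks (mm).
#' @return An object of class `marking_set`.
#' @export
marking_set <- function(extent_mm, nipple_xy = extent_mm[1:2] / 2,
                        areola_radius_mm = 12, mark_interval_mm = 20) {
  stopifnot(length(extent_mm) >= 2, length(nipple_xy) == 2)
  rays <- list(lateral = c(1, 0), medial = c(-1, 0),
               cranial = c(0, 1), caudal = c(0, -1))
  marks <- do.call(rbind, lapply(names(rays), function(nm) {
    dir <- rays[[nm]]
    # distance to the boundary along this ray
    lim <- ifelse(dir[1] != 0,
                  if (dir[1] > 0) extent_mm[1] - nipple_xy[1] else nipple_xy[1],
                  if (dir[2] > 0) extent_mm[2] - nipple_xy[2] else nipple_xy[2])
    if (lim < mark_interval_mm) return(NULL)
    d <- seq(mark_interval_mm, lim, by = mark_interval_mm)
    data.frame(ray = nm, x_mm = nipple_xy[1] + d * dir[1],
               y_mm = nipple_xy[2] + d * dir[2])
  }))
  structure(list(nipple_xy = as.numeric(nipple_xy),
                 areola_radius_mm = areola_radius_mm,
                 mark_interval_mm = mark_interval_mm,
                 marks = marks),
            class = "marking_set")
}

# grow one vessel polyline as a curvature-bounded random walk, reflected at
# the volume boundaries; the depth component mean-reverts to the seeding
# depth so each vessel stays in its stratum and the latent depth profile
# follows the seeding distribution
grow_polyline <- function(p0, dir0, length_mm, extent, step = 0.5, curv = 0.10) {
  nst <- max(1L, as.integer(ceiling(length_mm / step)))
  d <- dir0 / sqrt(sum(dir0^2))
  pert <- matrix(rnorm(3L * nst, 0, curv), ncol = 3)
  pert[, 3] <- pert[, 3] * 0.5
  pts <- matrix(0, nst + 1L, 3)
  pts[1, ] <- p0
  z0 <- p0[3]
  for (i in seq_len(nst)) {
    d <- d + pert[i, ]
    d[3] <- 0.85 * d[3] - 0.15 * tanh((pts[i, 3] - z0) / 1.5)
    d <- d / sqrt(sum(d^2))
    pts[i + 1L, ] <- pts[i, ] + d * step
  }
  # fold back into the volume (mirror reflection)
  for (ax in 1:3) {
    lo <- 0.1
    hi <- extent[ax] - 0.1
    r <- (pts[, ax] - lo) %% (2 * (hi - lo))
    pts[, ax] <- lo + pmin(r, 2 * (hi - lo) - r)
  }
  pts
}

polyline_segments <- function(pts, r) {
  n <- nrow(pts)
  if (n < 2) return(NULL)
  cbind(pts[-n, , drop = FALSE], pts[-1, , drop = FALSE], rep(r, n - 1))
}

#' Generate a synthetic vessel tree
#'
#' Grows vessels (curvature-bounded random walks with occasional bifurcation,
#' seeded preferentially near the surface) until the predicted binarised
#' en-face coverage of the 0–2.5 mm layer reaches the configured target.
#' Coverage is predicted by voxelising the tube geometry in the superficial
#' slab with the same rasteriser used by [render_volume()], so generation and
#' measurement agree by construction. Node diameters are drawn from the side's
#' effective anchors ([effective_anchors()]); each unbranched vessel carries a
#' constant caliber.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return An object of class `vessel_tree`: `segments` (list of polyline
#'   data.frames with `x_mm, y_mm, z_mm, diameter_mm`), `branch_points`
#'   (matrix), `total_length_mm`, and the generating extent/spacing.
#' @export
generate_vessel_tree <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  anchors <- effective_anchors(config)
  ext <- config$extent_mm
  sp <- config$spacing_mm
  nx <- as.integer(round(ext[1] / sp))
  ny <- as.integer(round(ext[2] / sp))
  foot <- logical(nx * ny)
  target_px <- config$coverage * nx * ny
  covered <- 0
  total_len <- 0
  segments <- list()
  branch_pts <- NULL

  if (config$length_budget_mm <= 0 || config$coverage == 0) {
    return(structure(list(segments = list(), branch_points = NULL,
                          total_length_mm = 0, extent_mm = ext, spacing_mm = sp),
                     class = "vessel_tree"))
  }

  queue <- list()
  while (covered < target_px) {
    if (total_len >= config$length_budget_mm)
      stop("coverage target unreachable within length budget (reached ",
           sprintf("%.1f%%", 100 * covered / (nx * ny)), " of the en-face plane)")
    if (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
    } else {
      z0 <- min(ext[3] - 0.3, 0.15 + rexp(1, 1 / config$depth_scale))
      az <- runif(1, 0, 2 * pi)
      v <- list(p0 = c(runif(1, 0, ext[1]), runif(1, 0, ext[2]), z0),
                dir = c(cos(az), sin(az), runif(1, -0.15, 0.15)),
                len = runif(1, 8, 20), gen = 1L)
    }
    pts <- grow_polyline(v$p0, v$dir, v$len, ext)
    r <- sample_diameters(1, anchors) / 2
    segs <- polyline_segments(pts, r)
    if (is.null(segs)) next
    newpix <- cpp_mark_footprint(segs, foot, c(nx, ny, 1L), sp, 0, 2.5)
    covered <- covered + newpix
    total_len <- total_len + v$len
    segments[[length(segments) + 1L]] <-
      data.frame(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3],
                 diameter_mm = 2 * r)
    # bifurcations: spawn first-generation children from random interior
    # nodes (no deeper cascade, to keep the spatial coverage well mixed)
    nin <- nrow(pts) - 2L
    if (nin > 0 && v$gen < 2L) {
      kb <- which(runif(nin) < 0.015) + 1L
      for (k in kb) {
        branch_pts <- rbind(branch_pts, pts[k, ])
        az2 <- runif(1, 0, 2 * pi)
        queue[[length(queue) + 1L]] <-
          list(p0 = pts[k, ], dir = c(cos(az2), sin(az2), runif(1, -0.15, 0.15)),
               len = runif(1, 6, 14), gen = v$gen + 1L)
      }
    }
  }
  structure(list(segments = segments, branch_points = branch_pts,
                 total_length_mm = total_len, extent_mm = ext, spacing_mm = sp),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d vessels, %.0f mm total centerline, %d branch points\n",
              length(x$segments), x$total_length_mm,
              if (is.null(x$branch_points)) 0L else nrow(x$branch_points)))
  invisible(x)
}

# all tube segments of a tree as one matrix (x1 y1 z1 x2 y2 z2 r)
tree_segment_matrix <- function(tree) {
  if (!length(tree$segments)) return(matrix(0, 0, 7))
  do.call(rbind, lapply(tree$segments, function(df) {
    pts <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")])
    polyline_segments(pts, df$diameter_mm[1] / 2)
  }))
}

#' Total centerline length of a tree within a depth slab
#'
#' @param tree A [generate_vessel_tree()] result.
#' @param z_lo,z_hi Depth interval (mm), half-open.
#' @return Length in mm.
#' @export
tree_length_in_slab <- function(tree, z_lo = 0, z_hi = 2.5) {
  segs <- tree_segment_matrix(tree)
  if (!nrow(segs)) return(0)
  # clip each segment to the slab by linear interpolation in z
  len <- 0
  for (i in seq_len(nrow(segs))) {
    z1 <- segs[i, 3]; z2 <- segs[i, 6]
    l <- sqrt(sum((segs[i, 4:6] - segs[i, 1:3])^2))
    if (z1 == z2) {
      if (z1 >= z_lo && z1 < z_hi) len <- len + l
      next
    }
    t1 <- (z_lo - z1) / (z2 - z1)
    t2 <- (z_hi - z1) / (z2 - z1)
    t_lo <- min(1, max(0, min(t1, t2)))
    t_hi <- min(1, max(0, max(t1, t2)))
    if (t_hi > t_lo) len <- len + l * (t_hi - t_lo)
  }
  len
}

#' Render a vessel tree into an intensity volume
#'
#' Rasterises each vessel as a tube of its local diameter; vessel voxels carry
#' intensity `amplitude * exp(-mu_eff * depth)`, the tissue background carries
#' a constant baseline, and Gaussian noise is added everywhere before clipping
#' to the 8-bit range. If a contact defect is configured, the affected columns
#' are displaced into the volume by the gap depth (air above reads 0).
#'
#' @param tree A [generate_vessel_tree()] result.
#' @param config The generating [phantom_config()].
#' @param box Optional sub-box to render: `list(origin_mm = c(x, y),
#'   extent_mm = c(x, y))` en-face; depth always starts at 0.
#' @param zmax_mm Optional depth truncation (mm) for render passes that only
#'   need the optically visible range.
#' @return A [pa_volume()] with 8-bit integer data.
#' @export
render_volume <- function(tree, config, box = NULL, zmax_mm = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  sp <- config$spacing_mm
  ext <- config$extent_mm
  if (is.null(box)) {
    origin <- c(0, 0, 0)
    bext <- ext
  } else {
    origin <- c(box$origin_mm[1:2], 0)
    bext <- c(box$extent_mm[1:2], ext[3])
    if (any(origin[1:2] < -1e-9) || any(origin[1:2] + bext[1:2] > ext[1:2] + 1e-9))
      stop("render box exceeds the volume extent")
  }
  if (!is.null(zmax_mm)) bext[3] <- min(bext[3], zmax_mm)
  dims <- as.integer(round(bext / sp))
  n <- prod(dims)

  mask <- logical(n)
  segs <- tree_segment_matrix(tree)
  if (nrow(segs)) cpp_raster_tubes(segs, mask, dims, sp, origin)

  zc <- (seq_len(dims[3]) - 0.5) * sp
  vess <- config$amplitude * exp(-config$mu_eff * zc)
  a <- array(rnorm(n, config$bg_level, config$noise_sd), dims)
  dim(mask) <- dims
  for (k in seq_len(dims[3])) {
    mk <- mask[, , k]
    if (any(mk)) {
      sl <- a[, , k]
      sl[mk] <- sl[mk] + vess[k]
      a[, , k] <- sl
    }
  }
  a <- pmin(255, pmax(0, a))
  a <- array(as.integer(floor(a + 0.5)), dims)

  if (!is.null(config$contact_defect)) {
    gap_vox <- as.integer(round(config$contact_defect$gap_mm / sp))
    # defect strip along low-x side of the full en-face plane
    cut_mm <- config$contact_defect$fraction * ext[1]
    x_mm <- origin[1] + (seq_len(dims[1]) - 0.5) * sp
    cols <- which(x_mm < cut_mm)
    if (length(cols) && gap_vox > 0 && gap_vox < dims[3]) {
      a[cols, , (gap_vox + 1):dims[3]] <- a[cols, , 1:(dims[3] - gap_vox)]
      a[cols, , 1:gap_vox] <- 0L
    }
  }
  pa_volume(a, sp)
}

#' Render the binarised vessel mask directly
#'
#' Samples the binarised image straight from the generative model, without
#' materialising intensities: thresholding the noisy render is a per-voxel
#' Bernoulli event, so shallow vessel voxels (whose attenuated signal clears
#' the threshold with certainty) need no random draw, deeper vessel voxels
#' get one Bernoulli draw with the per-slice exceedance probability, and the
#' rare background false-positives are scattered by sampling their count.
#' The result is distributed identically to
#' `binarize(to_grayscale(render_volume(...)), threshold)` at a fraction of
#' the cost; use it where only the mask is needed (diameter measurement).
#' Falls back to the full intensity render when a contact defect is
#' configured.
#'
#' @param tree A [generate_vessel_tree()] result.
#' @param config The generating [phantom_config()].
#' @param threshold Binarisation threshold.
#' @param box,zmax_mm As in [render_volume()].
#' @return A logical [pa_volume()] mask.
#' @export
render_mask <- function(tree, config, threshold = 75, box = NULL, zmax_mm = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(config$contact_defect))
    return(binarize(to_grayscale(render_volume(tree, config, box = box,
                                               zmax_mm = zmax_mm)), threshold))
  sp <- config$spacing_mm
  ext <- config$extent_mm
  if (is.null(box)) {
    origin <- c(0, 0, 0)
    bext <- ext
  } else {
    origin <- c(box$origin_mm[1:2], 0)
    bext <- c(box$extent_mm[1:2], ext[3])
    if (any(origin[1:2] < -1e-9) || any(origin[1:2] + bext[1:2] > ext[1:2] + 1e-9))
      stop("render box exceeds the volume extent")
  }
  if (!is.null(zmax_mm)) bext[3] <- min(bext[3], zmax_mm)
  dims <- as.integer(round(bext / sp))
  zc <- (seq_len(dims[3]) - 0.5) * sp
  vess_mean <- config$bg_level + config$amplitude * exp(-config$mu_eff * zc)
  # a stored value v binarises to foreground iff v + noise >= threshold + 0.5
  p_vess <- stats::pnorm(threshold + 0.5, mean = vess_mean,
                         sd = config$noise_sd, lower.tail = FALSE)
  p_vess[p_vess > 1 - 1e-12] <- 1
  p_bg <- stats::pnorm(threshold + 0.5, mean = config$bg_level,
                       sd = config$noise_sd, lower.tail = FALSE)
  segs <- tree_segment_matrix(tree)
  m <- cpp_render_mask(segs, dims, sp, origin, p_vess, p_bg)
  pa_volume(array(as.logical(m), dims), sp)
}

#' Optically resolvable depth of a phantom configuration
#'
#' The depth at which the attenuated vessel signal sinks so far below the
#' binarisation threshold that vessels are no longer reliably segmentable
#' (amplitude falls below threshold - background - one noise sd). Deeper
#' voxels contribute only fragmented, noise-gated traces; diameter
#' measurement is restricted to this range.
#'
#' @param config A [phantom_config()].
#' @param threshold Binarisation threshold.
#' @return Depth in mm (the full extent when attenuation is off).
#' @export
visible_depth <- function(config, threshold = 75) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$mu_eff <= 0) return(config$extent_mm[3])
  margin <- max(threshold - config$bg_level - config$noise_sd, 5)
  min(config$extent_mm[3], log(config$amplitude / margin) / config$mu_eff)
}

#' Simulate one paired imaging case
#'
#' Generates the reconstructed and contralateral volumes of one case with
#' ground-truth vessel trees and the marking model, fully reproducible from
#' one master seed (stage sub-seeds are derived by fixed offsets).
#'
#' @param config_recon,config_contra Side configs sharing extent and spacing.
#' @param interval_months Postoperative interval; applied to both configs
#'   (only the reconstructed side remodels).
#' @param seed Master seed for the case.
#' @param case_id Case identifier (defaults to the seed).
#' @param render Logical: rasterise full volumes (set `FALSE` to keep only
#'   ground-truth trees, e.g. for ROI-box rendering downstream).
#' @return An object of class `case_bundle`.
#' @export
make_case <- function(config_recon, config_contra, interval_months, seed,
                      case_id = NULL, render = TRUE) {
  stopifnot(inherits(config_recon, "phantom_config"),
            inherits(config_contra, "phantom_config"))
  if (config_recon$side != "reconstructed" || config_contra$side != "contralateral")
    stop("config sides must be reconstructed / contralateral respectively")
  if (!isTRUE(all.equal(config_recon$extent_mm, config_contra$extent_mm)) ||
      config_recon$spacing_mm != config_contra$spacing_mm)
    stop("both side configs must share extent and spacing")
  if (interval_months < 0) stop("interval must be >= 0")
  config_recon$interval_months <- interval_months
  config_contra$interval_months <- interval_months
  base <- as.integer(seed %% 1000003L)
  sides <- list()
  offs <- c(reconstructed = 0L, contralateral = 32L)
  cfgs <- list(reconstructed = config_recon, contralateral = config_contra)
  for (s in names(cfgs)) {
    tree <- generate_vessel_tree(cfgs[[s]], seed = base * 2048L + offs[[s]] + 1L)
    vol <- NULL
    if (render) {
      set.seed(base * 2048L + offs[[s]] + 2L)
      vol <- render_volume(tree, cfgs[[s]])
    }
    sides[[s]] <- list(config = cfgs[[s]], tree = tree, volume = vol)
  }
  structure(list(case_id = case_id %||% as.character(seed),
                 interval_months = interval_months,
                 seed = seed,
                 reconstructed = sides$reconstructed,
                 contralateral = sides$contralateral,
                 markings = marking_set(config_recon$extent_mm,
                                        areola_radius_mm = config_recon$areola_radius_mm)),
            class = "case_bundle")
}
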