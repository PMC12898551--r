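#' Study configuration
#'
#' Bundles everything needed for a reproducible synthetic study: per-case
#' postoperative intervals, the paired phantom parameters, the analysis
#' parameters, and the master seed from which all per-case and per-stage
#' seeds are derived by fixed offsets.
#'
#' @param intervals_months Integer vector, one postoperative interval per
#'   case.
#' @param seed Master seed.
#' @param extent_mm,spacing_mm Phantom geometry (see [phantom_config()]).
#' @param coverage_recon,coverage_contra Superficial coverage targets.
#' @param remodeling_rate Anchor shrinkage per month on the reconstructed
#'   side.
#' @param anchors Baseline diameter distribution.
#' @param defects Optional named list mapping case index (as character) to a
#'   contact-defect spec (`list(gap_mm =, fraction =)`) applied to both sides
#'   of that case.
#' @param threshold Binarisation threshold.
#' @param surface_threshold,tolerance_mm,min_contact Surface/QC parameters.
#' @param density_method Density counting convention.
#' @param stages Subset of `c("density", "caliber")` to run.
#' @param mu_eff,amplitude,bg_level,noise_sd,depth_scale,areola_radius_mm
#'   Forwarded to [phantom_config()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(intervals_months, seed = 1,
                         extent_mm = c(80, 80, 20), spacing_mm = 0.125,
                         coverage_recon = 0.282, coverage_contra = 0.198,
                         remodeling_rate = 0.01,
                         anchors = quantile_anchors(),
                         defects = NULL,
                         threshold = 75, surface_threshold = 20,
                         tolerance_mm = 0.5, min_contact = 0.9,
                         density_method = c("projection", "voxel"),
                         stages = c("density", "caliber"),
                         mu_eff = 0.15, amplitude = 240, bg_level = 28,
                         noise_sd = 12, depth_scale = 6,
                         areola_radius_mm = 12) {
  if (!length(intervals_months)) stop("at least one case interval is required")
  if (any(intervals_months < 0)) stop("intervals must be >= 0 months")
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(intervals_months = as.integer(intervals_months),
                 seed = as.integer(seed),
                 extent_mm = extent_mm, spacing_mm = spacing_mm,
                 coverage_recon = coverage_recon,
                 coverage_contra = coverage_contra,
                 remodeling_rate = remodeling_rate, anchors = anchors,
                 defects = defects, threshold = threshold,
                 surface_threshold = surface_threshold,
                 tolerance_mm = tolerance_mm, min_contact = min_contact,
                 density_method = match.arg(density_method),
                 stages = stages, mu_eff = mu_eff, amplitude = amplitude,
                 bg_level = bg_level, noise_sd = noise_sd,
                 depth_scale = depth_scale,
                 areola_radius_mm = areola_radius_mm),
            class = "study_config")
}

side_phantom_config <- function(sc, side, interval, defect) {
  phantom_config(side = side, extent_mm = sc$extent_mm,
                 spacing_mm = sc$spacing_mm,
                 coverage = if (side == "reconstructed") sc$coverage_recon else sc$coverage_contra,
                 anchors = sc$anchors, interval_months = interval,
                 remodeling_rate = sc$remodeling_rate, mu_eff = sc$mu_eff,
                 amplitude = sc$amplitude, bg_level = sc$bg_level,
                 noise_sd = sc$noise_sd, depth_scale = sc$depth_scale,
                 contact_defect = defect,
                 areola_radius_mm = sc$areola_radius_mm)
}

# measure one side's ROIs by rendering only the four ROI boxes (used when the
# full volume is not materialised)
measure_side_from_tree <- function(tree, cfg, markings, specs, threshold,
                                   render_seed) {
  out <- list()
  set.seed(render_seed)
  zmax <- visible_depth(cfg, threshold)
  for (sp in specs) {
    box <- list(origin_mm = c(sp$x_mm[1], sp$y_mm[1]),
                extent_mm = c(diff(sp$x_mm), diff(sp$y_mm)))
    roi <- render_mask(tree, cfg, threshold, box = box, zmax_mm = zmax)
    df <- measure_diameters(roi)
    if (nrow(df)) {
      df$x_mm <- df$x_mm + box$origin_mm[1]
      df$y_mm <- df$y_mm + box$origin_mm[2]
      df$quadrant <- sp$label
      out[[sp$label]] <- df
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run a full synthetic study
#'
#' Simulates every case, applies contact QC, computes depth-density profiles
#' for QC-passed cases, measures vessel diameters on all cases, derives
#' caliber cutoffs from the pooled contralateral measurements, classifies,
#' computes side differences and interval trends, and assembles the study
#' report. A failure in one case is recorded and the run continues (partial
#' studies are valid outputs, mirroring per-endpoint case subsets).
#'
#' Everything is reproducible from the master seed: per-case seeds are
#' `seed * 1000 + case index`, and each generation/render stage re-seeds with
#' a fixed offset, so reruns are bit-identical.
#'
#' @param sc A [study_config()].
#' @param out_dir Optional directory for the CSV/JSON report artifacts
#'   (created if missing); see [write_report()].
#' @return A `study_report` (see [build_report()]) with an added `cutoffs`
#'   element and per-case `errors` (if any).
#' @export
run_study <- function(sc, out_dir = NULL) {
  stopifnot(inherits(sc, "study_config"))
  n <- length(sc$intervals_months)
  records <- vector("list", n)
  samples <- list()
  errors <- list()
  want_density <- "density" %in% sc$stages
  want_caliber <- "caliber" %in% sc$stages

  for (i in seq_len(n)) {
    interval <- sc$intervals_months[i]
    defect <- if (!is.null(sc$defects)) sc$defects[[as.character(i)]] else NULL
    cfg_r <- side_phantom_config(sc, "reconstructed", interval, defect)
    cfg_c <- side_phantom_config(sc, "contralateral", interval, defect)
    case_seed <- sc$seed * 1000L + i
    rec <- list(case_id = i, interval_months = interval)
    ok <- tryCatch({
      bundle <- make_case(cfg_r, cfg_c, interval, seed = case_seed,
                          case_id = as.character(i), render = want_density)
      if (want_density) {
        pr <- tryCatch(
          side_profiles(bundle, threshold = sc$threshold,
                        surface_threshold = sc$surface_threshold,
                        tolerance_mm = sc$tolerance_mm,
                        min_contact = sc$min_contact,
                        method = sc$density_method),
          pavasc_qc_exclusion = function(e) e)
        if (inherits(pr, "pavasc_qc_exclusion")) {
          rec$qc <- pr$qc
          rec$profiles <- NULL
        } else {
          rec$qc <- pr$qc
          rec$profiles <- pr
        }
      }
      if (want_caliber) {
        quads <- divide_quadrants(bundle$markings, cfg_r$extent_mm)
        specs <- select_rois(bundle$markings, quads)
        base <- as.integer(case_seed %% 1000003L)
        offs <- c(reconstructed = 0L, contralateral = 32L)
        for (s in c("reconstructed", "contralateral")) {
          if (!is.null(bundle[[s]]$volume)) {
            df <- measure_side(bundle[[s]]$volume, bundle$markings, sc$threshold,
                               zmax_mm = visible_depth(bundle[[s]]$config,
                                                       sc$threshold))
          } else {
            df <- measure_side_from_tree(bundle[[s]]$tree, bundle[[s]]$config,
                                         bundle$markings, specs, sc$threshold,
                                         render_seed = base * 2048L + offs[[s]] + 3L)
          }
          if (!is.null(df) && nrow(df)) {
            df$case <- as.character(i)
            df$side <- s
            df$interval_months <- interval
            samples[[paste(i, s)]] <- df
          }
        }
      }
      TRUE
    }, error = function(e) {
      errors[[as.character(i)]] <<- conditionMessage(e)
      FALSE
    })
    records[[i]] <- rec
  }

  cutoffs <- NULL
  if (want_caliber && length(samples)) {
    all_samples <- do.call(rbind, samples)
    rownames(all_samples) <- NULL
    contra <- all_samples$diameter_mm[all_samples$side == "contralateral"]
    cutoffs <- tryCatch(derive_cutoffs(contra), error = function(e) {
      errors$cutoffs <<- conditionMessage(e)
      NULL
    })
    if (!is.null(cutoffs)) {
      props <- caliber_proportions(all_samples, cutoffs)
      for (i in seq_len(n)) {
        pi <- props[props$case == as.character(i), , drop = FALSE]
        if (nrow(pi) == 2) records[[i]]$proportions <- pi
      }
    }
  }

  report <- build_report(records)
  report$cutoffs <- cutoffs
  report$samples <- if (want_caliber && length(samples)) all_samples else NULL
  report$errors <- errors
  report$config <- sc
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write study report artifacts
#'
#' Writes `profiles.csv`, `proportions.csv`, `differences.csv`, `trends.csv`,
#' `summary.csv`, `qc.csv`, and a `manifest.json` recording the seed, the
#' full configuration and its hash, so every output is regenerable from the
#' manifest alone. Rerunning the same configuration produces byte-identical
#' files.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(report$profiles, "profiles.csv")
  wr(report$proportions, "proportions.csv")
  wr(report$differences, "differences.csv")
  wr(report$trends, "trends.csv")
  wr(report$summary, "summary.csv")
  wr(report$qc, "qc.csv")
  cfg <- report$config
  cfg$anchors <- list(probs = cfg$anchors$probs, diameters = cfg$anchors$diameters)
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "pavasc",
    version = as.character(utils::packageVersion("pavasc")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    cutoffs = if (!is.null(report$cutoffs)) unclass(report$cutoffs) else NULL,
    errors = report$errors)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
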