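# shared fixtures: hand-built vessel trees and small phantom configs

# a vessel tree holding straight tube(s); pts_list = list of n x 3 matrices
manual_tree <- function(pts_list, diameters_mm, extent_mm, spacing_mm) {
  segs <- lapply(seq_along(pts_list), function(i) {
    p <- pts_list[[i]]
    data.frame(x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3],
               diameter_mm = diameters_mm[i])
  })
  structure(list(segments = segs, branch_points = NULL,
                 total_length_mm = sum(vapply(pts_list, function(p) {
                   sum(sqrt(rowSums(diff(p)^2)))
                 }, numeric(1))),
                 extent_mm = extent_mm, spacing_mm = spacing_mm),
            class = "vessel_tree")
}

# straight cylinder along x at given depth
cylinder_tree <- function(diameter_mm, depth_mm, extent_mm = c(12, 12, 20),
                          spacing_mm = 0.125, y_mm = extent_mm[2] / 2 + 0.06) {
  pts <- cbind(seq(1.5, extent_mm[1] - 1.5, by = 0.5), y_mm, depth_mm)
  manual_tree(list(pts), diameter_mm, extent_mm, spacing_mm)
}

quiet_config <- function(extent_mm = c(12, 12, 20), spacing_mm = 0.125,
                         mu_eff = 0, ...) {
  phantom_config("contralateral", extent_mm = extent_mm,
                 spacing_mm = spacing_mm, coverage = 0, mu_eff = mu_eff, ...)
}

# render a manual tree to a clean binary mask (negligible noise)
render_clean_mask <- function(tree, config, threshold = 75) {
  config$noise_sd <- 1e-6
  render_mask(tree, config, threshold = threshold)
}
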