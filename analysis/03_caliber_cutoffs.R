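#!/usr/bin/env Rscript
# Vessel-caliber measurement and quartile-anchored cutoffs.
#
# First derives the classification cutoffs from a pooled synthetic
# contralateral diameter sample (n = 2008), then runs the automated
# skeleton/distance-transform measurement on one rendered case pair and
# compares the measured distribution with the ground-truth calibers.

suppressPackageStartupMessages(library(pavasc))

out_dir <- "results/caliber"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

## cutoffs from the pooled synthetic sample ---------------------------------
d <- sample_diameters(2008, seed = 42)
cs <- derive_cutoffs(d)
cat(sprintf("pooled synthetic sample (n = %d): quartiles %.3f / %.3f / %.3f mm\n",
            cs$n, cs$q1, cs$median, cs$q3))
cat(sprintf("rounded classification cutoffs: %.1f mm and %.1f mm\n\n",
            cs$lower, cs$upper))
jsonlite::write_json(unclass(cs), file.path(out_dir, "cutoffs.json"),
                     auto_unbox = TRUE, digits = NA)

## automated measurement on one rendered case -------------------------------
cfg_r <- phantom_config("reconstructed", interval_months = 26)
cfg_c <- phantom_config("contralateral", interval_months = 26)
bundle <- make_case(cfg_r, cfg_c, interval_months = 26, seed = 2001,
                    render = FALSE)
mk <- bundle$markings
specs <- select_rois(mk, divide_quadrants(mk, cfg_r$extent_mm))

samples <- list()
for (s in c("reconstructed", "contralateral")) {
  cfg <- bundle[[s]]$config
  set.seed(3000 + (s == "reconstructed"))
  for (sp in specs) {
    box <- list(origin_mm = c(sp$x_mm[1], sp$y_mm[1]), extent_mm = c(30, 30))
    m <- render_mask(bundle[[s]]$tree, cfg, box = box,
                     zmax_mm = visible_depth(cfg))
    df <- measure_diameters(m)
    if (nrow(df)) {
      df$side <- s
      df$quadrant <- sp$label
      samples[[paste(s, sp$label)]] <- df
    }
  }
  truth <- unlist(lapply(bundle[[s]]$tree$segments, function(x) x$diameter_mm[1]))
  meas <- do.call(rbind, samples[grep(s, names(samples))])
  cat(sprintf("%s: %d measurements; measured median %.3f mm (ground-truth vessel median %.3f mm)\n",
              s, nrow(meas), median(meas$diameter_mm), median(truth)))
}
all_meas <- do.call(rbind, samples)
rownames(all_meas) <- NULL
write.csv(all_meas, file.path(out_dir, "measurements.csv"), row.names = FALSE)

props <- caliber_proportions(
  data.frame(diameter_mm = all_meas$diameter_mm, side = all_meas$side), cs)
write.csv(props, file.path(out_dir, "proportions.csv"), row.names = FALSE)
cat("\nclass proportions against the synthetic-sample cutoffs:\n")
print(props, row.names = FALSE)
cat("\nwrote", file.path(out_dir, "measurements.csv"), "and proportions.csv\n")
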