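#!/usr/bin/env Rscript
# Depth-stratified vascular density on five simulated case pairs.
#
# Runs the full density pipeline (surface detection, contact QC, periareolar
# ROI extraction, grayscale + binarisation at 75, half-open 2.5 mm layers)
# on five simulated case pairs and writes the per-layer profiles plus a
# depth-profile figure. The superficial layer should show the reconstructed >
# contralateral contrast the phantom is calibrated to.

suppressPackageStartupMessages({
  library(pavasc)
  library(ggplot2)
})

out_dir <- "results/density"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

rows <- list()
for (i in 1:5) {
  cfg_r <- phantom_config("reconstructed", spacing_mm = 0.25)
  cfg_c <- phantom_config("contralateral", spacing_mm = 0.25)
  bundle <- make_case(cfg_r, cfg_c, interval_months = 0, seed = 1000L + i,
                      case_id = i)
  prof <- side_profiles(bundle)
  for (s in c("reconstructed", "contralateral")) {
    sch <- depth_layers()
    rows[[paste(i, s)]] <- data.frame(
      case = i, side = s, layer = sch$layer,
      depth_mm = (sch$lo_mm + sch$hi_mm) / 2,
      density_pct = prof[[s]]$density_pct)
  }
  cat(sprintf("case %d: layer-1 %.1f%% vs %.1f%%\n", i,
              prof$reconstructed$density_pct[1],
              prof$contralateral$density_pct[1]))
}
profiles <- do.call(rbind, rows)
write.csv(profiles, file.path(out_dir, "profiles.csv"), row.names = FALSE)

l1 <- subset(profiles, layer == 1)
cat(sprintf("\nmean superficial density: %.2f%% reconstructed, %.2f%% contralateral\n",
            mean(l1$density_pct[l1$side == "reconstructed"]),
            mean(l1$density_pct[l1$side == "contralateral"])))

p <- ggplot(profiles, aes(depth_mm, density_pct, colour = side)) +
  geom_line() + geom_point(size = 1) +
  facet_wrap(~case, nrow = 1) +
  scale_colour_manual(values = c(reconstructed = "#E69F00",
                                 contralateral = "#0072B2")) +
  labs(x = "depth from skin surface (mm)", y = "vascular density (%)",
       title = "Depth profiles of binarised vascular density (5 simulated cases)") +
  theme_minimal(base_size = 10)
ggsave(file.path(out_dir, "depth_profiles.png"), p, width = 10, height = 2.8,
       dpi = 150)
cat("wrote", file.path(out_dir, "profiles.csv"), "and depth_profiles.png\n")
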