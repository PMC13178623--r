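#!/usr/bin/env Rscript
# Stage 5: fiber orientations relative to the tumor invasive front.
#
# Acute angles between collagen orientations and the local boundary tangent
# are collected in a peritumoral band for the tangential ("low WPOI") and
# radial ("high WPOI") phantoms, summarized as violins, and compared: the
# radial arrangement must show the larger perpendicular fraction.

suppressPackageStartupMessages(library(comsli))

data_dir <- "results/data"
out_dir <- "results"
band_width <- 20   # pixels; matches the phantoms' collagen band

cat("== relative orientation analysis ==\n")
dists <- list()
for (arr in c("tangential", "radial", "mixed")) {
  st <- read_angular_stack(file.path(data_dir,
                                     sprintf("stack_tumor_%s.tif", arr)))
  om <- compute_orientation_map(st)
  bd <- read_boundary(file.path(data_dir, sprintf("boundary_%s.json", arr)))
  tg <- resample_and_tangents(bd, spacing = 2)
  band <- peritumoral_band(bd, band_width, dim(om$valid), side = "outside")
  rel <- relative_orientation_map(om, tg, band)
  write_rgb_image(colorize_relative_fom(rel),
                  file.path("results/maps", sprintf("relative_fom_%s.png", arr)))
  write.csv(data.frame(delta_deg = rel$samples),
            file.path(out_dir, sprintf("delta_samples_%s.csv", arr)),
            row.names = FALSE)
  dists[[arr]] <- distribution_summary(rel$samples)
  cat(sprintf("  %-11s n = %5d, median = %5.1f deg, perpendicular fraction = %.3f\n",
              arr, dists[[arr]]$n, dists[[arr]]$median,
              dists[[arr]]$perpendicular_fraction))
}

cmp <- compare_phenotypes(dists$tangential, dists$radial)
print(cmp)

summary_df <- do.call(rbind, lapply(names(dists), function(a) {
  d <- dists[[a]]
  data.frame(arrangement = a, n = d$n, median = d$median, q1 = d$q1,
             q3 = d$q3, perpendicular_fraction = d$perpendicular_fraction)
}))
write.csv(summary_df, file.path(out_dir, "relative_orientation_summary.csv"),
          row.names = FALSE)

p <- plot_orientation_violin(list(`low WPOI\n(tangential)` = dists$tangential,
                                  `high WPOI\n(radial)` = dists$radial,
                                  mixed = dists$mixed))
ggplot2::ggsave(file.path(out_dir, "relative_orientation_violin.png"), p,
                width = 5, height = 4, dpi = 150)
cat("wrote results/relative_orientation_summary.csv and violin figure\n")
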