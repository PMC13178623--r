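#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study material.
#
# Known-truth orientation fields are rendered into the measurement modalities
# the rest of the workflow consumes: multi-angle scattering stacks (24 frames,
# 15-degree steps), a four-angle polarization stack, a picrosirius-red-like
# RGB scan, and tumor phantoms with tangential ("low WPOI") versus radial
# ("high WPOI") peritumoral collagen.

suppressPackageStartupMessages(library(comsli))

seed <- 20260929
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

model <- scatter_model()  # 24 angles, sigma 20 deg, baseline 0.1, noise 0.02

cat("== simulating phantoms ==\n")

# single-fiber field at 35 deg and a 20/110 crossing
f_const <- make_orientation_field("constant", 64, 64, list(theta = 35))
write_angular_stack(render_scatter_stack(f_const, model, seed = seed),
                    file.path(data_dir, "stack_constant35.tif"), seed = seed,
                    provenance = "constant-field phantom, theta = 35 deg")

f_cross <- make_orientation_field("two_region_crossing", 64, 96,
                                  list(theta1 = 20, theta2 = 110))
write_angular_stack(render_scatter_stack(f_cross, model, seed = seed + 1),
                    file.path(data_dir, "stack_crossing.tif"), seed = seed + 1,
                    provenance = "two-region crossing phantom, 20/110 deg")

# tumor phantoms: tangential vs radial vs mixed peritumoral collagen
for (arr in c("tangential", "radial", "mixed")) {
  params <- list(radius = 45, band_width = 20, arrangement = arr)
  if (arr == "mixed") params$mixed_fraction <- 0.3
  f <- make_orientation_field("tumor_phantom", 160, 160, params,
                              seed = seed + 2)
  st <- render_scatter_stack(f, model, seed = seed + 3)
  write_angular_stack(st, file.path(data_dir, sprintf("stack_tumor_%s.tif", arr)),
                      seed = seed + 3,
                      provenance = sprintf("tumor phantom, %s collagen", arr))
  write_boundary(boundary_annotation(attr(f, "boundary")),
                 file.path(data_dir, sprintf("boundary_%s.json", arr)))
  write_mask(attr(f, "band"), file.path(data_dir, sprintf("band_%s.png", arr)))
  cat(sprintf("  tumor phantom (%s): %d band pixels\n", arr,
              sum(attr(f, "band"))))
}

# polarization stack over a retardance/azimuth gradient
az <- matrix(rep(seq(0, 179, length.out = 96), each = 64), 64, 96)
ret <- matrix(rep(seq(0.2, 1, length.out = 64), times = 96), 64, 96)
write_pli_stack(render_pli_stack(ret, az, transmittance = 2),
                file.path(data_dir, "pli_gradient.tif"))

# PSR-like slide of the mixed phantom's collagen band
f_mix <- make_orientation_field("tumor_phantom", 160, 160,
                                list(radius = 45, band_width = 20,
                                     arrangement = "mixed",
                                     mixed_fraction = 0.3), seed = seed + 2)
collagen_truth <- attr(f_mix, "band")
write_mask(collagen_truth, file.path(data_dir, "collagen_truth.png"))
write_rgb_image(render_psr_image(collagen_truth, seed = seed + 4),
                file.path(data_dir, "psr_mixed.png"))

cat(sprintf("wrote synthetic material to %s (seed %d)\n", data_dir, seed))
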