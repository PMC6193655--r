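#!/usr/bin/env Rscript
# Stage 2: derive the 12 terrain covariates from the DEM and sample them at
# the plot locations.
#
# Covariates: relative elevation Hr, slope beta, aspect A, cosA, sinA,
# slope-of-slope Cv, slope-of-aspect Ch, local relief QFD, roughness M,
# relative position index RPI, wetness index TWI, stream-power index SPI.
#
# Inputs : results/dem.asc, results/samples.csv (stage 1)
# Outputs: results/terrain/<name>.asc, results/plot_covariates.csv

library(soilfertmap)

dem <- read_ascii_grid("results/dem.asc")
samples <- read_samples("results/samples.csv")

stack <- terrain_stack(dem)
dir.create("results/terrain", showWarnings = FALSE, recursive = TRUE)
for (nm in covariate_names())
  write_ascii_grid(stack[[nm]], file.path("results/terrain",
                                          paste0(nm, ".asc")))

plots <- unique(samples[, c("plot_id", "x", "y")])
covs <- cbind(plots, sample_covariates(stack, plots))
write.csv(covs, "results/plot_covariates.csv", row.names = FALSE)

cat("Terrain stack written for", paste(dim(dem), collapse = " x "),
    "cells; covariates sampled at", nrow(plots), "plots\n")
cat("Ranges:\n")
for (nm in covariate_names()) {
  v <- stack[[nm]]$values
  cat(sprintf("  %-5s [%8.3f, %8.3f]\n", nm, min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
}
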