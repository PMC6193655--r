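#!/usr/bin/env Rscript
# Stage 4: ordinary-kriging and regression-kriging surfaces for every
# property x layer over the full grid.
#
# OK kriges the (possibly log-transformed) values directly; RK fits a
# stepwise terrain drift (entry/stay at P < 0.05, VIF cap 10), kriges its
# residuals and adds the drift back. Log-scale fits are back-transformed by
# plain exponentiation.
#
# Inputs : results/dem.asc, results/samples.csv
# Outputs: results/maps/<property>_<layer>_{OK,RK}.asc,
#          results/drift_models.csv

library(soilfertmap)

dem <- read_ascii_grid("results/dem.asc")
samples <- read_samples("results/samples.csv")
stack <- terrain_stack(dem)
mod <- samples[samples$subset == "modelling", ]
dir.create("results/maps", showWarnings = FALSE, recursive = TRUE)

drift_rows <- list()
for (p in unique(mod$property)) for (l in unique(mod$layer)) {
  tab <- mod[mod$property == p & mod$layer == l, ]
  td <- transform_decision(tab$value)
  logs <- td$scale == "log"
  wtab <- data.frame(x = tab$x, y = tab$y, value = td$values)
  vm <- fit_variogram(empirical_variogram(wtab$x, wtab$y, wtab$value))
  ok <- ok_predict(wtab, vm, dem, log_scale = logs)
  rk <- rk_predict(wtab, stack, dem, log_scale = logs)
  dmod <- rk$drift_model
  if (logs) {
    ok <- back_transform(ok)
    rk <- back_transform(rk)
  }
  tag <- sprintf("%s_%s", p, gsub("-", "_", l))
  write_ascii_grid(ok$pred, sprintf("results/maps/%s_OK.asc", tag))
  write_ascii_grid(rk$pred, sprintf("results/maps/%s_RK.asc", tag))
  drift_rows[[length(drift_rows) + 1L]] <- data.frame(
    property = p, layer = l, scale = td$scale,
    covariates = paste(dmod$selected, collapse = " + "),
    r_squared = round(dmod$r_squared, 4),
    press = signif(dmod$press, 4))
  cat(sprintf("[%s %s] drift: %s (R^2 = %.2f)\n", p, l,
              if (length(dmod$selected)) paste(dmod$selected, collapse = " + ")
              else "(intercept only)", dmod$r_squared))
}
drift <- do.call(rbind, drift_rows)
write.csv(drift, "results/drift_models.csv", row.names = FALSE)
if (requireNamespace("jsonlite", quietly = TRUE))
  jsonlite::write_json(drift, "results/drift_models.json", dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
cat("Wrote", 2 * nrow(drift), "prediction rasters under results/maps/\n")
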