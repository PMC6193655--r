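#!/usr/bin/env Rscript
# Stage 6: comprehensive soil-fertility surfaces.
#
# For each layer, the eight preferred prediction surfaces (stage 5's method
# choice applied to stage 4's rasters) are non-dimensionalized to Fi scores,
# combined by the improved minimum-based Nemerow index
# F = sqrt((mean^2 + min^2)/2) * 7/8, classified (I >= 2.70 > II >= 1.80 >
# III >= 0.90 > IV) and summarized as area fractions. Note the index
# amendment caps F at 2.625 for eight properties, so class I cannot occur.
#
# Inputs : results/maps/*.asc (stage 4), results/validation.csv (stage 5)
# Outputs: results/F_<layer>.asc, results/Fclass_<layer>.asc,
#          results/area_fractions.csv

library(soilfertmap)

val <- read.csv("results/validation.csv")
dir.create("results", showWarnings = FALSE)

frac_rows <- list()
for (l in unique(val$layer)) {
  tag <- gsub("-", "_", l)
  surfaces <- list()
  for (p in unique(val$property)) {
    meth <- val$preferred[val$property == p & val$layer == l]
    surfaces[[p]] <- read_ascii_grid(
      sprintf("results/maps/%s_%s_%s.asc", p, tag, meth))
  }
  fr <- suppressWarnings(fertility_surface(surfaces))
  write_ascii_grid(fr$F, sprintf("results/F_%s.asc", tag))
  cls_num <- raster_grid(
    matrix(match(fr$class$values, c("I", "II", "III", "IV")),
           nrow(fr$F$values)),
    fr$F$xll, fr$F$yll, fr$F$cellsize)
  write_ascii_grid(cls_num, sprintf("results/Fclass_%s.asc", tag))
  for (k in names(fr$fractions))
    frac_rows[[length(frac_rows) + 1L]] <- data.frame(
      layer = l, class = k, fraction = fr$fractions[[k]])
  cat(sprintf("[%s cm] mean F = %.3f; classes: %s\n", l,
              mean(fr$F$values, na.rm = TRUE),
              paste(sprintf("%s %.1f%%", names(fr$fractions),
                            100 * fr$fractions), collapse = ", ")))
}
fracs <- do.call(rbind, frac_rows)
write.csv(fracs, "results/area_fractions.csv", row.names = FALSE)
cat("Fertility surfaces and area fractions written under results/\n")
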