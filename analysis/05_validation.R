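#!/usr/bin/env Rscript
# Stage 5: leave-one-out cross-validation of OK and RK for every property x
# layer, and per-property method selection.
#
# Every held-out fit redoes the whole chain (transform decision, variogram,
# stepwise drift) without the held-out plot. Errors are computed on the
# measurement scale. The method with the lower RMSE is preferred (ties:
# lower MRE, then lower |ME|, then OK).
#
# Inputs : results/dem.asc, results/samples.csv
# Outputs: results/validation.csv (ME/MRE/RMSE for both methods + preferred)

library(soilfertmap)

dem <- read_ascii_grid("results/dem.asc")
samples <- read_samples("results/samples.csv")
stack <- terrain_stack(dem)
mod <- samples[samples$subset == "modelling", ]

rows <- list()
for (p in unique(mod$property)) for (l in unique(mod$layer)) {
  tab <- mod[mod$property == p & mod$layer == l, ]
  ok_pred <- suppressWarnings(loocv(tab, "OK"))
  rk_pred <- suppressWarnings(loocv(tab, "RK", stack))
  keep <- is.finite(ok_pred) & is.finite(rk_pred)
  rep <- select_method(error_stats(tab$value[keep], ok_pred[keep]),
                       error_stats(tab$value[keep], rk_pred[keep]),
                       property = p, layer = l)
  rows[[length(rows) + 1L]] <- data.frame(
    property = p, layer = l,
    ok_me = round(rep$ok$me, 4), ok_mre = round(rep$ok$mre, 4),
    ok_rmse = round(rep$ok$rmse, 4),
    rk_me = round(rep$rk$me, 4), rk_mre = round(rep$rk$mre, 4),
    rk_rmse = round(rep$rk$rmse, 4),
    preferred = rep$preferred)
  cat(sprintf("[%s %s] RMSE OK %.4f vs RK %.4f -> %s\n", p, l,
              rep$ok$rmse, rep$rk$rmse, rep$preferred))
}
out <- do.call(rbind, rows)
write.csv(out, "results/validation.csv", row.names = FALSE)
cat(sprintf("RK preferred for %d of %d property-layers\n",
            sum(out$preferred == "RK"), nrow(out)))
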