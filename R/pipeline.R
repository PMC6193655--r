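# Workflow orchestration: simulate -> terrain -> variogram -> krige (OK and
# RK) -> validate/select -> fertility, with a manifest sufficient to re-run
# the whole analysis bit-identically.

#' Read a plot-sample table from CSV
#'
#' Expects at least plot_id, x, y, value columns; rows with missing or
#' non-numeric coordinates are rejected with their row numbers.
#'
#' @param path CSV path.
#' @return data.frame of samples.
#' @export
read_samples <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plot_id", "x", "y", "value")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("x", "y", "value")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad))
      stop("column ", col, " has missing/non-numeric entries in rows: ",
           paste(bad, collapse = ", "))
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}

#' Write a plot-sample table to CSV
#'
#' @param table sample data.frame.
#' @param path CSV path.
#' @export
write_samples <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a study configuration as YAML
#'
#' @param config a `study_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  ser <- unclass(config)
  ser$properties <- lapply(ser$properties, function(pr) {
    pr$vmodel <- pr$vmodel[c("kind", "nugget", "psill", "range")]
    pr$drift <- as.list(pr$drift)
    pr
  })
  ser$vegetation_effects <- lapply(ser$vegetation_effects, as.list)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' @param path YAML path.
#' @return a `study_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  props <- lapply(raw$properties, function(pr) {
    pr$vmodel <- variogram_model(pr$vmodel$kind, pr$vmodel$nugget,
                                 pr$vmodel$psill, pr$vmodel$range)
    pr$drift <- unlist(pr$drift)
    pr$layer_offsets <- as.numeric(pr$layer_offsets)
    pr
  })
  veg <- lapply(raw$vegetation_effects, unlist)
  study_config(grid = as.numeric(raw$grid), cellsize = raw$cellsize,
               seed = raw$seed, n = raw$n, split = raw$split,
               noise_sd = raw$noise_sd, properties = props,
               vegetation_effects = veg, roughness = raw$roughness)
}

# fit-and-predict for one property/layer: transform decision, variogram,
# OK and RK surfaces over the DEM grid, validation, method selection
run_property_layer <- function(tab, stack, template, validation, back,
                               n_lags, max_dist) {
  td <- transform_decision(tab$value)
  log_scale <- td$scale == "log"
  wtab <- data.frame(x = tab$x, y = tab$y, value = td$values)
  emp <- empirical_variogram(wtab$x, wtab$y, wtab$value, n_lags, max_dist)
  vm <- fit_variogram(emp, "auto")
  ok_surf <- ok_predict(wtab, vm, template, log_scale = log_scale)
  rk_surf <- rk_predict(wtab, stack, template, n_lags = n_lags,
                        max_dist = max_dist, log_scale = log_scale)
  if (log_scale) {
    ok_surf <- back_transform(ok_surf, back)
    rk_surf <- back_transform(rk_surf, back)
  }
  if (validation == "loocv") {
    obs <- tab$value
    ok_pred <- loocv(tab, "OK", n_lags = n_lags, max_dist = max_dist,
                     back = back)
    rk_pred <- loocv(tab, "RK", stack, n_lags = n_lags, max_dist = max_dist,
                     back = back)
  } else {
    stop("unknown validation mode: ", validation)
  }
  keep <- is.finite(ok_pred) & is.finite(rk_pred)
  ok_err <- error_stats(obs[keep], ok_pred[keep])
  rk_err <- error_stats(obs[keep], rk_pred[keep])
  list(vmodel = vm, scale = td$scale, skewness = td$skewness,
       ok = ok_surf, rk = rk_surf,
       report = select_method(ok_err, rk_err))
}

# split-sample validation: fit on the modelling subset, score held-out
# validation plots
run_property_layer_split <- function(mod, val, stack, template, back,
                                     n_lags, max_dist) {
  td <- transform_decision(mod$value)
  log_scale <- td$scale == "log"
  wtab <- data.frame(x = mod$x, y = mod$y, value = td$values)
  emp <- empirical_variogram(wtab$x, wtab$y, wtab$value, n_lags, max_dist)
  vm <- fit_variogram(emp, "auto")
  targets <- val[, c("x", "y")]
  ok_surf <- ok_predict(wtab, vm, template, log_scale = log_scale)
  rk_surf <- rk_predict(wtab, stack, template, n_lags = n_lags,
                        max_dist = max_dist, log_scale = log_scale)
  ok_p <- ok_predict(wtab, vm, targets, log_scale = log_scale)
  rk_p <- rk_predict(wtab, stack, targets, n_lags = n_lags,
                     max_dist = max_dist, log_scale = log_scale)
  if (log_scale) {
    ok_surf <- back_transform(ok_surf, back)
    rk_surf <- back_transform(rk_surf, back)
    ok_p <- back_transform(ok_p, back)
    rk_p <- back_transform(rk_p, back)
  }
  list(vmodel = vm, scale = td$scale, skewness = td$skewness,
       ok = ok_surf, rk = rk_surf,
       report = select_method(error_stats(val$value, surface_values(ok_p)),
                              error_stats(val$value, surface_values(rk_p))))
}

class_to_numeric <- function(cls) {
  m <- matrix(match(cls, c("I", "II", "III", "IV")), nrow(cls))
  m
}

#' Run the full hybrid mapping workflow
#'
#' Generates (or accepts) a synthetic study, then for every property x
#' layer: decides the log transform, fits the variogram, builds OK and RK
#' surfaces over the DEM grid, validates both methods, selects the
#' preferred one, and finally combines the preferred per-property surfaces
#' into the comprehensive fertility index per layer. All randomness derives
#' from the config seed, so two runs with the same config are
#' bit-identical.
#'
#' @param config a `study_config`.
#' @param study optionally a pre-built `synthetic_study` (must match config).
#' @param outdir directory for rasters/CSV/manifest; tempdir-backed when
#'   NULL (checksums still computed).
#' @param validation "loocv" (leave-one-out on the modelling plots, the
#'   default) or "split" (score the held-out validation plots).
#' @param back back-transform mode for log-scale fits.
#' @param n_lags,max_dist empirical-variogram binning.
#' @return object of class `run_manifest`: variogram fits, Table-9-style
#'   method selection table, per-layer fertility area fractions, output
#'   paths and raster checksums.
#' @export
run_all <- function(config = study_config(), study = NULL, outdir = NULL,
                    validation = c("loocv", "split"), back = "naive",
                    n_lags = 12, max_dist = NULL) {
  validation <- match.arg(validation)
  if (is.null(study)) study <- make_study(config)
  if (is.null(outdir)) outdir <- tempfile("runall")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stack <- study$stack
  template <- study$dem
  props <- names(study$fields)
  layers <- soil_layers()
  fits <- list(); reports <- list(); preferred <- list()
  paths <- character()
  put <- function(grid, name) {
    p <- file.path(outdir, paste0(name, ".asc"))
    write_ascii_grid(grid, p)
    paths[[name]] <<- p
    p
  }
  for (p in props) {
    preferred[[p]] <- list()
    for (l in layers) {
      tab <- study$samples[study$samples$property == p &
                             study$samples$layer == l, ]
      mod <- tab[tab$subset == "modelling", ]
      res <- if (validation == "loocv") {
        run_property_layer(mod, stack, template, validation, back,
                           n_lags, max_dist)
      } else {
        run_property_layer_split(mod, tab[tab$subset == "validation", ],
                                 stack, template, back, n_lags, max_dist)
      }
      vm <- res$vmodel
      fits[[length(fits) + 1L]] <- data.frame(
        property = p, layer = l, scale = res$scale,
        kind = vm$kind, nugget = vm$nugget, psill = vm$psill,
        range = vm$range, ns_ratio = vm$ns_ratio, dependency = vm$class)
      rep <- res$report; rep$property <- p; rep$layer <- l
      reports[[length(reports) + 1L]] <- rep
      tag <- sprintf("%s_%s", p, gsub("-", "_", l))
      put(surface_values_grid(res$ok), paste0(tag, "_OK"))
      put(surface_values_grid(res$rk), paste0(tag, "_RK"))
      preferred[[p]][[l]] <-
        if (rep$preferred == "RK") res$rk else res$ok
      message(sprintf(
        "[%s %s cm] %s fit (C0=%.3g C=%.3g a=%.3g, N/S %s) -> %s",
        p, l, vm$kind, vm$nugget, vm$psill, vm$range, vm$class,
        rep$preferred))
    }
  }
  fert <- list()
  for (l in layers) {
    surfs <- lapply(preferred, function(pp) pp[[l]]$pred)
    fr <- fertility_surface(surfs)
    fert[[l]] <- fr
    put(fr$F, sprintf("F_%s", gsub("-", "_", l)))
    put(raster_grid(class_to_numeric(fr$class$values),
                    template$xll, template$yll, template$cellsize),
        sprintf("Fclass_%s", gsub("-", "_", l)))
  }
  write_samples(study$samples, file.path(outdir, "samples.csv"))
  write_config(config, file.path(outdir, "config.yaml"))
  method_table <- do.call(rbind, lapply(reports, function(r) data.frame(
    property = r$property, layer = r$layer,
    ok_me = r$ok$me, ok_mre = r$ok$mre, ok_rmse = r$ok$rmse,
    rk_me = r$rk$me, rk_mre = r$rk$mre, rk_rmse = r$rk$rmse,
    preferred = r$preferred)))
  structure(list(
    config = config, seed = config$seed, validation = validation,
    variograms = do.call(rbind, fits),
    methods = method_table,
    fractions = lapply(fert, function(f) f$fractions),
    fertility = fert,
    preferred = preferred,
    outdir = outdir, paths = paths,
    checksums = stats::setNames(tools::md5sum(unlist(paths)), names(paths))),
    class = "run_manifest")
}

surface_values_grid <- function(surf) {
  if (inherits(surf$pred, "raster_grid")) surf$pred
  else stop("surface does not hold a grid")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: %d property-layer fits (%s validation)\n",
              nrow(x$variograms), x$validation))
  cat(sprintf("  RK preferred for %d of %d property-layers\n",
              sum(x$methods$preferred == "RK"), nrow(x$methods)))
  for (l in names(x$fractions)) {
    fr <- x$fractions[[l]]
    cat(sprintf("  %s cm F classes: %s\n", l,
                paste(sprintf("%s %.1f%%", names(fr), 100 * fr),
                      collapse = ", ")))
  }
  invisible(x)
}
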