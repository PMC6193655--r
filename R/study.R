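# The synthetic study design: eight soil chemical properties observed in
# three depth layers at shared plots over one landscape, each property a
# terrain-drifted, variogram-structured random field.

soil_properties <- function() c("TN", "TP", "TK", "AN", "AP", "AK", "OM", "pH")

soil_layers <- function() c("0-20", "20-40", "40-60")

vegetation_levels <- function()
  c("BM", "CL", "EF", "GL", "PON", "POP", "PT", "QW", "RP", "SW")

# per-property generating recipes.  Units: TN/TP/TK/OM g/kg, AN/AP/AK
# mg/kg, pH unitless.  `lognormal` properties are simulated on the natural-
# log scale and exponentiated (right-skewed, high-CV nutrients).  Layer
# offsets shift the intercept for the 20-40 and 40-60 cm layers;
# `depth_decreasing` marks properties whose layer means must be strictly
# ordered.  Drift coefficients act on the simulation scale.
default_properties <- function() {
  vm <- function(C0, C, a) variogram_model("spherical", C0, C, a)
  list(
    TN = list(lognormal = FALSE, depth_decreasing = TRUE,
              drift = c("(Intercept)" = 1.187, RPI = -0.485, sinA = -0.132),
              vmodel = vm(0.02, 0.07, 600),
              layer_offsets = c(0, -0.45, -0.57)),
    TP = list(lognormal = FALSE, depth_decreasing = TRUE,
              drift = c("(Intercept)" = 0.557, Ch = 0.00138, beta = 0.00386),
              vmodel = vm(0.004, 0.012, 500),
              layer_offsets = c(0, -0.05, -0.10)),
    TK = list(lognormal = FALSE, depth_decreasing = FALSE,
              drift = c("(Intercept)" = 13.267, Hr = -0.00572),
              vmodel = vm(0.3, 1.2, 700),
              layer_offsets = c(0, 6.9, -0.15)),
    AN = list(lognormal = TRUE, depth_decreasing = TRUE,
              drift = c("(Intercept)" = 1.05, M = 2.2, sinA = -0.25),
              vmodel = vm(0.05, 0.35, 500),
              layer_offsets = c(0, -0.51, -0.88)),
    AP = list(lognormal = TRUE, depth_decreasing = FALSE,
              drift = c("(Intercept)" = 1.35, RPI = -0.45),
              vmodel = vm(0.04, 0.28, 450),
              layer_offsets = c(0, -0.29, -0.34)),
    AK = list(lognormal = FALSE, depth_decreasing = TRUE,
              drift = c("(Intercept)" = 85, A = -0.107, M = 51.4),
              vmodel = vm(250, 900, 600),
              layer_offsets = c(0, -37, -51)),
    OM = list(lognormal = TRUE, depth_decreasing = TRUE,
              drift = c("(Intercept)" = 3.3, RPI = -0.5, TWI = -0.08),
              vmodel = vm(0.05, 0.25, 550),
              layer_offsets = c(0, -0.51, -0.77)),
    pH = list(lognormal = FALSE, depth_decreasing = FALSE,
              drift = c("(Intercept)" = 7.68),
              vmodel = vm(0.01, 0.06, 800),
              layer_offsets = c(0, 0.18, 0.29)))
}

# additive vegetation-category offsets on the simulation scale; properties
# not listed get zero effects.  Natural forests (QW, PON, BM) enriched in
# TN, OM, AN, AK; cultivated/economic land depleted.
default_vegetation_effects <- function() {
  lv <- vegetation_levels()
  eff <- function(...) {
    v <- stats::setNames(rep(0, length(lv)), lv)
    dots <- c(...)
    v[names(dots)] <- dots
    v
  }
  list(TN = eff(BM = 0.12, PON = 0.12, QW = 0.15, CL = -0.10, EF = -0.08,
                RP = -0.05),
       OM = eff(BM = 0.15, PON = 0.15, QW = 0.20, CL = -0.12, EF = -0.10,
                RP = -0.08, POP = 0.05),
       AN = eff(BM = 0.15, PON = 0.15, QW = 0.20, CL = -0.10, EF = -0.08),
       AK = eff(BM = 8, PON = 8, QW = 10, CL = -8, EF = -6, RP = -4))
}

#' Synthetic study configuration
#'
#' Defaults define the study conditions: a 64 x 64-cell, 30 m landscape
#' (~1.9 x 1.9 km), 95 plots split 70/25 into modelling and validation
#' subsets, eight properties x three depth layers with terrain drift,
#' spherical residual variograms, depth-ordered layer means, additive
#' vegetation-cover effects and noise-free plot values.
#'
#' @param grid c(rows, cols), both >= 16.
#' @param cellsize cell size (m).
#' @param seed global seed recorded in the config.
#' @param n number of plots (>= 10).
#' @param split modelling fraction of plots (70/95 by default).
#' @param noise_sd plot measurement-noise SD (default 0).
#' @param properties per-property recipes (see the package vignette).
#' @param vegetation_effects per-property additive category offsets.
#' @param roughness DEM hill amplitude multiplier.
#' @return object of class `study_config`.
#' @export
study_config <- function(grid = c(64, 64), cellsize = 30, seed = 20141018,
                         n = 95, split = 70 / 95, noise_sd = 0,
                         properties = default_properties(),
                         vegetation_effects = default_vegetation_effects(),
                         roughness = 1) {
  if (any(grid < 16)) stop("grid must be at least 16 x 16")
  if (cellsize <= 0) stop("cellsize must be > 0")
  if (n < 10) stop("n must be >= 10")
  for (p in names(properties)) {
    pr <- properties[[p]]
    off <- pr$layer_offsets
    if (length(off) != 3) stop(p, ": need 3 layer offsets")
    if (isTRUE(pr$depth_decreasing) && any(diff(off) >= 0))
      stop(p, ": declared depth-decreasing but layer offsets not strictly ",
           "decreasing")
  }
  structure(list(grid = grid, cellsize = cellsize, seed = seed, n = n,
                 split = split, noise_sd = noise_sd,
                 properties = properties,
                 vegetation_effects = vegetation_effects,
                 roughness = roughness),
            class = "study_config")
}

#' Generate a full synthetic study
#'
#' Builds the DEM and terrain stack, draws shared plot locations with
#' vegetation labels and a modelling/validation split, and simulates every
#' property x layer field. Layers of one property share the structured
#' residual field (soil profiles are vertically correlated; the plots are
#' resampled at depth, not relocated) with independent per-layer nugget
#' noise, so declared depth-decreasing properties have strictly ordered
#' layer means by construction. Fully deterministic under the config seed.
#'
#' @param config a `study_config`.
#' @return object of class `synthetic_study`: config, dem, stack, fields
#'   (per property/layer `true_field`s, simulation scale), and `samples`,
#'   a long data.frame (plot_id, x, y, layer, property, value, subset,
#'   vegetation) on the measurement scale.
#' @export
make_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) stop("config must be a study_config")
  dem <- generate_dem(config$grid, config$cellsize,
                      roughness = config$roughness, seed = config$seed)
  stack <- terrain_stack(dem)
  ncell <- prod(config$grid)
  if (config$n > ncell) stop("n exceeds the number of grid cells")
  cc <- grid_coords(dem)
  lv <- vegetation_levels()
  with_seed(config$seed + 1L, {
    idx <- sample.int(ncell, config$n)
    veg <- sample(lv, config$n, replace = TRUE)
    nm <- round(config$n * config$split)
    sub <- sample(rep(c("modelling", "validation"),
                      c(nm, config$n - nm)))
  })
  rows <- cc$row[idx]; cols <- cc$col[idx]
  props <- names(config$properties)
  layers <- soil_layers()
  fields <- list()
  samples <- list()
  for (pi in seq_along(props)) {
    p <- props[pi]
    pr <- config$properties[[p]]
    # one structured residual per property, reused across layers
    res_field <- simulate_field(stack, pr$drift,
                                variogram_model(pr$vmodel$kind, 0,
                                                pr$vmodel$psill,
                                                pr$vmodel$range),
                                seed = config$seed + 101L * pi)
    res <- res_field$residual$values
    veg_eff <- config$vegetation_effects[[p]]
    if (is.null(veg_eff)) veg_eff <- stats::setNames(rep(0, length(lv)), lv)
    fields[[p]] <- list()
    for (li in seq_along(layers)) {
      coeffs <- pr$drift
      icpt <- which(names(coeffs) %in% c("(Intercept)", "intercept", ""))
      coeffs[icpt[1]] <- coeffs[icpt[1]] + pr$layer_offsets[li]
      fld <- simulate_field(stack, coeffs,
                            variogram_model(pr$vmodel$kind,
                                            pr$vmodel$nugget, 0, 1),
                            seed = config$seed + 1000L * pi + li)
      # splice in the shared structured residual
      g <- fld$truth
      fld$residual <- raster_grid(res, g$xll, g$yll, g$cellsize)
      fld$truth <- raster_grid(fld$drift$values + res + fld$nugget$values,
                               g$xll, g$yll, g$cellsize)
      fld$lognormal <- isTRUE(pr$lognormal)
      fields[[p]][[layers[li]]] <- fld
      simv <- fld$truth$values[cbind(rows, cols)] + veg_eff[veg]
      if (config$noise_sd > 0) {
        with_seed(config$seed + 7919L * pi + li,
                  simv <- simv + stats::rnorm(config$n, 0, config$noise_sd))
      }
      samples[[length(samples) + 1L]] <- data.frame(
        plot_id = seq_len(config$n), x = cc$x[idx], y = cc$y[idx],
        layer = layers[li], property = p,
        value = if (isTRUE(pr$lognormal)) exp(simv) else unname(simv),
        subset = sub, vegetation = veg)
    }
  }
  structure(list(config = config, dem = dem, stack = stack, fields = fields,
                 samples = do.call(rbind, samples)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d x %d grid, %d plots, %d properties x %d layers\n",
    x$config$grid[1], x$config$grid[2], x$config$n,
    length(x$fields), length(soil_layers())))
  invisible(x)
}
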