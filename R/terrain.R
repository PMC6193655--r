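# Terrain covariates derived from a DEM: slope, aspect and their trig forms,
# slope-of-slope and slope-of-aspect curvature proxies, relative elevation,
# local relief, surface roughness, D8 wetness/stream-power indices and the
# valley-to-ridge relative position index.

#' Canonical names of the 12 terrain covariates
#'
#' @return character vector, in stack order.
#' @export
covariate_names <- function() {
  c("Hr", "beta", "A", "cosA", "sinA", "Cv", "Ch", "QFD", "M", "RPI",
    "TWI", "SPI")
}

# central-difference gradient (one-sided at edges); fy is the derivative
# toward north (decreasing row index).  `circular` treats values as angles
# in degrees wrapping at 360 (used for slope-of-aspect).
grad_xy <- function(z, cellsize, circular = FALSE) {
  nr <- nrow(z); nc <- ncol(z)
  dif <- if (circular) function(a, b) ((a - b + 180) %% 360 - 180)
         else function(a, b) a - b
  right <- cbind(z[, -1, drop = FALSE], z[, nc])
  left  <- cbind(z[, 1], z[, -nc, drop = FALSE])
  up    <- rbind(z[1, ], z[-nr, , drop = FALSE])
  down  <- rbind(z[-1, , drop = FALSE], z[nr, ])
  span <- matrix(2 * cellsize, nr, nc)
  span[, c(1, nc)] <- cellsize
  fx <- dif(right, left) / span
  span <- matrix(2 * cellsize, nr, nc)
  span[c(1, nr), ] <- cellsize
  fy <- dif(up, down) / span
  list(fx = fx, fy = fy)
}

# the slope operator: gradient magnitude converted to degrees
slope_op <- function(z, cellsize, circular = FALSE) {
  g <- grad_xy(z, cellsize, circular)
  atan(sqrt(g$fx^2 + g$fy^2)) * 180 / pi
}

#' Slope and aspect from a DEM
#'
#' Finite-difference (3x3 neighbourhood) slope in degrees and aspect as the
#' compass azimuth of steepest descent, clockwise from north. Flat cells get
#' NA aspect (and NA cosA/sinA).
#'
#' @param dem a `raster_grid` DEM with at least 3x3 valid cells.
#' @return list of raster grids: beta (degrees), A (degrees, [0, 360)),
#'   cosA, sinA.
#' @export
slope_aspect <- function(dem) {
  z <- dem$values
  if (all(!is.finite(z))) stop("DEM has no valid cells")
  if (nrow(z) < 3 || ncol(z) < 3) stop("DEM must be at least 3x3")
  g <- grad_xy(z, dem$cellsize)
  beta <- atan(sqrt(g$fx^2 + g$fy^2)) * 180 / pi
  A <- (atan2(-g$fx, -g$fy) * 180 / pi) %% 360
  flat <- g$fx == 0 & g$fy == 0
  A[flat] <- NA_real_
  mk <- function(v) raster_grid(v, dem$xll, dem$yll, dem$cellsize)
  list(beta = mk(beta), A = mk(A),
       cosA = mk(cos(A * pi / 180)), sinA = mk(sin(A * pi / 180)))
}

#' Curvature proxies: slope of slope and slope of aspect
#'
#' Cv applies the slope operator to the slope grid (a proxy for vertical
#' curvature); Ch applies it to the aspect grid with circular differences
#' (aspect wraps at 360 degrees), a proxy for horizontal curvature.
#'
#' @param beta slope grid (degrees), from [slope_aspect()].
#' @param A aspect grid (degrees), from [slope_aspect()].
#' @return list of raster grids Cv, Ch.
#' @export
curvature_proxies <- function(beta, A) {
  mk <- function(v) raster_grid(v, beta$xll, beta$yll, beta$cellsize)
  list(Cv = mk(slope_op(beta$values, beta$cellsize)),
       Ch = mk(slope_op(A$values, A$cellsize, circular = TRUE)))
}

#' Relative elevation, local relief and surface roughness
#'
#' Hr = (global maximum elevation) - elevation; QFD = max - min over a
#' moving window; M = 1 / cos(slope in radians), the surface-roughness
#' factor (1 on flat ground, increasing with slope).
#'
#' @param dem a `raster_grid` DEM.
#' @param window odd window width >= 3 for QFD.
#' @return list of raster grids Hr, QFD, M.
#' @export
relief <- function(dem, window = 3) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  Hr <- max(z, na.rm = TRUE) - z
  half <- (window - 1) / 2
  hi <- matrix(-Inf, nr, nc); lo <- matrix(Inf, nr, nc)
  for (dr in -half:half) for (dc in -half:half) {
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    s <- z[rs, cs, drop = FALSE]
    hi <- pmax(hi, s, na.rm = TRUE)
    lo <- pmin(lo, s, na.rm = TRUE)
  }
  QFD <- hi - lo
  beta <- slope_op(z, dem$cellsize)
  M <- 1 / cos(beta * pi / 180)
  mk <- function(v) raster_grid(v, dem$xll, dem$yll, dem$cellsize)
  list(Hr = mk(Hr), QFD = mk(QFD), M = mk(M))
}

# Planchon-Darboux style iterative pit filling: lowers an initially flooded
# surface toward the DEM until every interior cell drains to the border with
# a minimal positive gradient.
fill_pits <- function(z, e = 1e-6) {
  nr <- nrow(z); nc <- ncol(z)
  W <- matrix(Inf, nr, nc)
  W[1, ] <- z[1, ]; W[nr, ] <- z[nr, ]; W[, 1] <- z[, 1]; W[, nc] <- z[, nc]
  pad <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    nbmin <- matrix(Inf, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nbmin <- pmin(nbmin, pad(W, dr, dc))
    }
    cand <- pmax(z, nbmin + e)
    if (all(cand >= W - 1e-12)) break
    W <- pmin(W, cand)
  }
  W
}

#' D8 flow accumulation and wetness/stream-power indices
#'
#' Fills pits, routes each cell's flow to its steepest-descent D8 neighbour,
#' accumulates contributing cell counts (including the cell itself) and
#' converts to specific catchment area As = count x cell size (area per unit
#' contour length). TWI = ln(As / max(tan beta, eps)); SPI = As x tan beta
#' (0 on flat cells).
#'
#' @param dem a `raster_grid` DEM.
#' @param eps floor for tan(beta) in TWI at flat cells.
#' @return list of raster grids As, TWI, SPI.
#' @export
flow_and_indices <- function(dem, eps = 1e-3) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); cs <- dem$cellsize
  W <- fill_pits(z)
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  dist <- sqrt(offs[, 1]^2 + offs[, 2]^2) * cs
  n <- nr * nc
  best_drop <- rep(0, n); down <- rep(NA_integer_, n)
  rows <- rep(seq_len(nr), times = nc); cols <- rep(seq_len(nc), each = nr)
  for (k in 1:8) {
    rn <- rows + offs[k, 1]; cn <- cols + offs[k, 2]
    ok <- rn >= 1 & rn <= nr & cn >= 1 & cn <= nc
    drop <- rep(-Inf, n)
    drop[ok] <- (W[cbind(rows[ok], cols[ok])] - W[cbind(rn[ok], cn[ok])]) /
      dist[k]
    upd <- drop > best_drop
    best_drop[upd] <- drop[upd]
    down[upd] <- (cn[upd] - 1L) * nr + rn[upd]
  }
  acc <- rep(1, n)
  ord <- order(W[cbind(rows, cols)], decreasing = TRUE)
  for (i in ord) {
    d <- down[i]
    if (!is.na(d)) acc[d] <- acc[d] + acc[i]
  }
  As <- matrix(NA_real_, nr, nc)
  As[cbind(rows, cols)] <- acc * cs
  tanb <- tan(slope_op(z, cs) * pi / 180)
  TWI <- log(As / pmax(tanb, eps))
  SPI <- As * tanb
  mk <- function(v) raster_grid(v, dem$xll, dem$yll, dem$cellsize)
  list(As = mk(As), TWI = mk(TWI), SPI = mk(SPI))
}

# Euclidean distance (map units) from every cell centre to the nearest TRUE
# cell of a mask, by direct minimization in blocks.
dist_to_mask <- function(grid, mask) {
  cc <- grid_coords(grid)
  mi <- which(mask[cbind(cc$row, cc$col)])
  if (!length(mi)) stop("mask has no cells")
  mx <- cc$x[mi]; my <- cc$y[mi]
  n <- nrow(cc)
  out <- numeric(n)
  block <- 4000L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(cc$x[s:e], mx, "-")^2 + outer(cc$y[s:e], my, "-")^2
    out[s:e] <- sqrt(apply(d2, 1L, min))
  }
  m <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  m[cbind(cc$row, cc$col)] <- out
  m
}

#' Relative position index (valley = 0, ridge = 1)
#'
#' Valley cells are high-flow-accumulation cells of the DEM; ridge cells are
#' high-accumulation cells of the inverted DEM (both thresholded at a
#' quantile of As). RPI = EDnv / (EDnv + EDnr) from the Euclidean distances
#' to the nearest valley and ridge cells.
#'
#' @param dem a `raster_grid` DEM.
#' @param quantile accumulation quantile defining valley/ridge cells.
#' @return list: RPI raster grid plus the logical valley/ridge masks.
#' @export
rpi <- function(dem, quantile = 0.95) {
  As_v <- flow_and_indices(dem)$As$values
  inv <- raster_grid(-dem$values, dem$xll, dem$yll, dem$cellsize)
  As_r <- flow_and_indices(inv)$As$values
  valley <- As_v >= stats::quantile(As_v, quantile, na.rm = TRUE)
  ridge <- As_r >= stats::quantile(As_r, quantile, na.rm = TRUE)
  if (!any(valley) || !any(ridge))
    stop("no valley or ridge cells extracted; lower the quantile threshold")
  dv <- dist_to_mask(dem, valley)
  dr <- dist_to_mask(dem, ridge)
  val <- ifelse(dv + dr == 0, 0.5, dv / (dv + dr))
  list(RPI = raster_grid(val, dem$xll, dem$yll, dem$cellsize),
       valley = valley, ridge = ridge)
}

#' Build the full 12-covariate terrain stack
#'
#' Derives Hr, beta, A, cosA, sinA, Cv, Ch, QFD, M, RPI, TWI and SPI (plus
#' the specific catchment area As as an intermediate) from a DEM, all on the
#' DEM's grid.
#'
#' @param dem a `raster_grid` DEM.
#' @param qfd_window moving-window width for QFD.
#' @param rpi_quantile accumulation quantile for valley/ridge extraction.
#' @param eps tan(beta) floor for TWI.
#' @return object of class `terrain_stack`: named list of aligned raster
#'   grids (and `dem`, `As`).
#' @export
terrain_stack <- function(dem, qfd_window = 3, rpi_quantile = 0.95,
                          eps = 1e-3) {
  sa <- slope_aspect(dem)
  cv <- curvature_proxies(sa$beta, sa$A)
  rl <- relief(dem, qfd_window)
  fl <- flow_and_indices(dem, eps)
  rp <- rpi(dem, rpi_quantile)
  st <- structure(c(list(dem = dem), rl["Hr"], sa, cv,
                    rl[c("QFD", "M")], list(RPI = rp$RPI),
                    fl[c("TWI", "SPI")], list(As = fl$As)),
                  class = "terrain_stack")
  check_aligned(st[covariate_names()])
  st
}

#' @export
print.terrain_stack <- function(x, ...) {
  cat(sprintf("terrain_stack: %d x %d cells, layers: %s\n",
              nrow(x$dem$values), ncol(x$dem$values),
              paste(covariate_names(), collapse = ", ")))
  invisible(x)
}

#' Sample all terrain covariates at point locations
#'
#' @param stack a `terrain_stack`.
#' @param points data.frame with columns x, y (map units).
#' @param method "nearest" (default) or "bilinear".
#' @return data.frame with one row per point and the 12 covariate columns.
#' @export
sample_covariates <- function(stack, points, method = "nearest") {
  out <- lapply(covariate_names(), function(nm)
    grid_extract(stack[[nm]], points$x, points$y, method))
  names(out) <- covariate_names()
  as.data.frame(out)
}
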