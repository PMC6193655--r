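# Seeded synthetic landscapes: DEM, spatially correlated property fields and
# plot samples carrying the statistical structure the mapping pipeline
# assumes (linear terrain drift + variogram-structured residual + nugget).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Generate a smooth synthetic DEM
#'
#' A tilted plane plus a seeded sum of smooth Gaussian hills and hollows:
#' a hill-and-valley surface with no nodata cells, deterministic under a
#' fixed seed. `roughness = 0` gives the bare plane.
#'
#' @param shape integer c(rows, cols), both >= 16.
#' @param cell_size cell edge length in metres.
#' @param roughness amplitude multiplier for the hills (metres of relief per
#'   unit; default 1 gives ~30-60 m of local relief on a 2 km extent).
#' @param seed RNG seed.
#' @param base_elev elevation offset (m).
#' @param base_slope c(dz/dx, dz/dy) of the underlying plane.
#' @param n_bumps number of Gaussian hills/hollows.
#' @return a `raster_grid` DEM.
#' @export
generate_dem <- function(shape = c(64, 64), cell_size = 30, roughness = 1,
                         seed = 1, base_elev = 1000,
                         base_slope = c(0.02, 0.015), n_bumps = 12) {
  if (length(shape) != 2 || any(shape < 16))
    stop("shape must be two integers, both >= 16")
  if (cell_size <= 0) stop("cell_size must be > 0")
  nr <- shape[1]; nc <- shape[2]
  ex <- nc * cell_size; ey <- nr * cell_size
  xs <- (seq_len(nc) - 0.5) * cell_size
  ys <- (nr - seq_len(nr) + 0.5) * cell_size
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  z <- base_elev + base_slope[1] * X + base_slope[2] * Y
  with_seed(seed, {
    cx <- stats::runif(n_bumps, 0, ex)
    cy <- stats::runif(n_bumps, 0, ey)
    w <- stats::runif(n_bumps, 0.08, 0.25) * max(ex, ey)
    amp <- stats::rnorm(n_bumps, 0, 25)
  })
  if (roughness > 0) {
    for (k in seq_len(n_bumps))
      z <- z + roughness * amp[k] *
        exp(-((X - cx[k])^2 + (Y - cy[k])^2) / (2 * w[k]^2))
  }
  raster_grid(z, xll = 0, yll = 0, cellsize = cell_size)
}

# zero-mean Gaussian random vector at arbitrary points with the structured
# (nugget-free) covariance of `vmodel`, by exact Cholesky factorization
grf_points <- function(x, y, vmodel, jitter = 1e-8) {
  n <- length(x)
  if (vmodel$psill == 0) return(rep(0, n))
  d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  K <- vgm_cov(vmodel, d)
  L <- try(chol(K + diag(jitter * vmodel$psill, n)), silent = TRUE)
  if (inherits(L, "try-error"))
    stop("covariance matrix for ", vmodel$kind, " model (a = ", vmodel$range,
         ") is not positive definite even after jitter")
  drop(crossprod(L, stats::rnorm(n)))
}

# grid realization by circulant embedding (FFT); used above the exact-solve
# cell budget.  Negative embedding eigenvalues are clamped to zero (slight
# covariance bias, warned once).
grf_grid_fft <- function(nr, nc, cellsize, vmodel) {
  M <- 2L * nr; N <- 2L * nc
  di <- pmin(0:(M - 1), M - (0:(M - 1))) * cellsize
  dj <- pmin(0:(N - 1), N - (0:(N - 1))) * cellsize
  D <- sqrt(outer(di^2, dj^2, "+"))
  Cm <- vgm_cov(vmodel, D)
  lam <- Re(stats::fft(Cm))
  if (min(lam) < -1e-8 * max(lam))
    warning("circulant embedding not nonnegative definite; ",
            "clamping negative eigenvalues")
  lam[lam < 0] <- 0
  eps <- matrix(complex(real = stats::rnorm(M * N),
                        imaginary = stats::rnorm(M * N)), M, N)
  Z <- stats::fft(sqrt(lam / (M * N)) * eps)
  Re(Z)[seq_len(nr), seq_len(nc)]
}

#' Simulate a property field over a terrain stack
#'
#' Truth = linear terrain drift + zero-mean correlated Gaussian residual
#' (covariance implied by the structured part of `vmodel`) + iid nugget
#' noise (variance = the model nugget C0). The three components are
#' retained separately so that truth = drift + residual + nugget exactly.
#'
#' @param stack a `terrain_stack`.
#' @param drift_coeffs named numeric vector of drift coefficients over stack
#'   layers; an unnamed or "(Intercept)" element is the intercept.
#' @param vmodel a `variogram_model` (spherical/exponential/gaussian).
#' @param seed RNG seed.
#' @param exact_max maximum cell count for exact covariance factorization;
#'   larger grids use the FFT circulant-embedding sampler.
#' @return object of class `true_field`: raster grids `truth`, `drift`,
#'   `residual`, `nugget`.
#' @export
simulate_field <- function(stack, drift_coeffs, vmodel, seed = 1,
                           exact_max = 4096) {
  tmpl <- stack$dem
  nr <- nrow(tmpl$values); nc <- ncol(tmpl$values)
  drift <- matrix(drift_intercept(drift_coeffs), nr, nc)
  for (nm in drift_names(drift_coeffs)) {
    if (is.null(stack[[nm]]))
      stop("drift coefficient references unknown covariate: ", nm)
    drift <- drift + drift_coeffs[[nm]] * stack[[nm]]$values
  }
  with_seed(seed, {
    if (vmodel$psill == 0) {
      res <- matrix(0, nr, nc)
    } else if (nr * nc <= exact_max) {
      cc <- grid_coords(tmpl)
      res <- matrix(NA_real_, nr, nc)
      res[cbind(cc$row, cc$col)] <- grf_points(cc$x, cc$y, vmodel)
    } else {
      res <- grf_grid_fft(nr, nc, tmpl$cellsize, vmodel)
    }
    nug <- if (vmodel$nugget > 0)
      matrix(stats::rnorm(nr * nc, 0, sqrt(vmodel$nugget)), nr, nc)
    else matrix(0, nr, nc)
  })
  g <- function(v) raster_grid(v, tmpl$xll, tmpl$yll, tmpl$cellsize)
  structure(list(truth = g(drift + res + nug), drift = g(drift),
                 residual = g(res), nugget = g(nug), vmodel = vmodel),
            class = "true_field")
}

drift_intercept <- function(coeffs) {
  nm <- names(coeffs)
  if (is.null(nm)) nm <- rep("", length(coeffs))
  i <- which(nm %in% c("", "(Intercept)", "intercept"))
  if (length(i)) sum(coeffs[i]) else 0
}

drift_names <- function(coeffs) {
  nm <- names(coeffs)
  if (is.null(nm)) return(character())
  setdiff(nm, c("", "(Intercept)", "intercept"))
}

#' Sample plot locations and values from a field
#'
#' Draws n distinct in-bounds cells, records their centre coordinates and the
#' true field value there, optionally adds measurement noise and tags a
#' modelling/validation split.
#'
#' @param field a `true_field` or `raster_grid`.
#' @param n number of plots (<= number of cells).
#' @param seed RNG seed.
#' @param scheme "random" (uniform over cells).
#' @param noise_sd measurement noise standard deviation (default 0: plot
#'   values are noise-free composites).
#' @param split optional modelling fraction in (0, 1); tags
#'   round(n * split) points "modelling", the rest "validation".
#' @return data.frame: plot_id, x, y, value, subset.
#' @export
sample_plots <- function(field, n, seed = 1, scheme = "random",
                         noise_sd = 0, split = NULL) {
  grid <- if (inherits(field, "true_field")) field$truth else field
  ncell <- length(grid$values)
  if (n > ncell) stop("n = ", n, " exceeds the ", ncell, " grid cells")
  scheme <- match.arg(scheme, "random")
  cc <- grid_coords(grid)
  with_seed(seed, {
    idx <- sample.int(ncell, n)
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
    sub <- if (!is.null(split)) {
      nm <- round(n * split)
      sample(rep(c("modelling", "validation"), c(nm, n - nm)))
    } else rep("modelling", n)
  })
  data.frame(plot_id = seq_len(n),
             x = cc$x[idx], y = cc$y[idx],
             value = grid$values[cbind(cc$row[idx], cc$col[idx])] + noise,
             subset = sub)
}

#' Simulate property values at point locations only
#'
#' Point-support version of [simulate_field()]: drift from covariates sampled
#' at the points plus an exact correlated Gaussian residual and nugget noise
#' at the points. Used by simulation studies that never need the full grid.
#'
#' @inheritParams simulate_field
#' @param points data.frame with columns x, y.
#' @return data.frame: x, y, value, drift, residual, nugget.
#' @export
simulate_samples <- function(stack, points, drift_coeffs, vmodel, seed = 1) {
  covs <- sample_covariates(stack, points)
  drift <- rep(drift_intercept(drift_coeffs), nrow(points))
  for (nm in drift_names(drift_coeffs))
    drift <- drift + drift_coeffs[[nm]] * covs[[nm]]
  with_seed(seed, {
    res <- grf_points(points$x, points$y, vmodel)
    nug <- if (vmodel$nugget > 0)
      stats::rnorm(nrow(points), 0, sqrt(vmodel$nugget))
    else rep(0, nrow(points))
  })
  data.frame(x = points$x, y = points$y, value = drift + res + nug,
             drift = drift, residual = res, nugget = nug)
}
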