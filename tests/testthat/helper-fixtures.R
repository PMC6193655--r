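# shared fixtures, built in code

# inclined plane DEM: z = gx * x + gy * y (+ base), cell-centre registered
plane_dem <- function(nr = 20, nc = 20, cs = 10, gx = 0.1, gy = 0,
                      base = 0) {
  xs <- matrix((seq_len(nc) - 0.5) * cs, nr, nc, byrow = TRUE)
  ys <- matrix((nr - seq_len(nr) + 0.5) * cs, nr, nc)
  raster_grid(base + gx * xs + gy * ys, cellsize = cs)
}

flat_dem <- function(nr = 16, nc = 16, cs = 5, z = 100)
  raster_grid(matrix(z, nr, nc), cellsize = cs)

# circular cone centred on the grid
cone_dem <- function(nr = 24, cs = 10, slope = 0.2) {
  xs <- matrix((seq_len(nr) - 0.5) * cs, nr, nr, byrow = TRUE)
  ys <- matrix((nr - seq_len(nr) + 0.5) * cs, nr, nr)
  cx <- nr * cs / 2; cy <- nr * cs / 2
  r <- sqrt((xs - cx)^2 + (ys - cy)^2)
  raster_grid(100 - slope * r, cellsize = cs)
}

# one cached terrain stack for tests that just need realistic covariates
test_stack <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- terrain_stack(generate_dem(c(48, 48), 30, seed = 97))
    memo
  }
})

# random sample table over a stack's extent (cell centres, no duplicates)
random_plots <- function(stack, n, seed) {
  sample_plots(stack$dem, n, seed = seed)
}

interior <- function(m) m[2:(nrow(m) - 1), 2:(ncol(m) - 1)]
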