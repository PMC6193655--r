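test_that("flat DEM: zero slope, undefined aspect, unit roughness, no relief", {
  dem <- flat_dem()
  sa <- slope_aspect(dem)
  expect_true(all(sa$beta$values == 0))
  expect_true(all(is.na(sa$A$values)))
  expect_true(all(is.na(sa$cosA$values)))
  rl <- relief(dem)
  expect_true(all(rl$QFD$values == 0))
  expect_true(all(rl$M$values == 1))
  expect_true(all(rl$Hr$values == 0))
})

test_that("inclined planes give the analytic slope and compass aspect", {
  # z = 0.1 x: steepest descent due west (270), slope atan(0.1)
  east <- plane_dem(gx = 0.1, gy = 0)
  sa <- slope_aspect(east)
  expect_equal(max(abs(sa$beta$values / (atan(0.1) * 180 / pi) - 1)), 0,
               tolerance = 1e-6)
  expect_true(all(sa$A$values == 270))
  # z = 0.1 y: descent due south (180)
  north <- plane_dem(gx = 0, gy = 0.1)
  expect_true(all(slope_aspect(north)$A$values == 180))
  # constant slope and aspect: curvature proxies vanish in the interior
  cv <- curvature_proxies(sa$beta, sa$A)
  expect_true(all(interior(cv$Cv$values) == 0))
  expect_true(all(interior(cv$Ch$values) == 0))
})

test_that("slope-of-slope on a cone equals re-applying the slope stencil", {
  dem <- cone_dem()
  sa <- slope_aspect(dem)
  cv <- curvature_proxies(sa$beta, sa$A)
  # independent re-application: loop-based central differences on beta
  b <- sa$beta$values; cs <- dem$cellsize
  nr <- nrow(b); nc <- ncol(b)
  expected <- matrix(NA_real_, nr, nc)
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    fx <- (b[r, c + 1] - b[r, c - 1]) / (2 * cs)
    fy <- (b[r - 1, c] - b[r + 1, c]) / (2 * cs)
    expected[r, c] <- atan(sqrt(fx^2 + fy^2)) * 180 / pi
  }
  expect_equal(interior(cv$Cv$values), interior(expected), tolerance = 1e-12)
})

test_that("window relief: hand-computed QFD and peak Hr", {
  toy <- raster_grid(matrix(1:9, 3, 3, byrow = TRUE), cellsize = 1)
  expect_equal(relief(toy)$QFD$values[2, 2], 8)
  dem <- cone_dem()  # inverted cone has its peak at the centre-ish maximum
  peak <- which(dem$values == max(dem$values), arr.ind = TRUE)[1, ]
  expect_equal(relief(dem)$Hr$values[peak[1], peak[2]], 0)
})

test_that("D8 accumulation on a one-direction plane matches the hand trace", {
  # z decreases westward: every cell drains due west along its row, so a
  # cell in column j collects the (nc - j) cells east of it plus itself
  dem <- plane_dem(8, 8, cs = 10, gx = 0.1, gy = 0)
  fl <- flow_and_indices(dem)
  nc <- 8
  for (j in 2:7)
    expect_equal(fl$As$values[4, j], (nc - j + 1) * dem$cellsize)
})

test_that("TWI and SPI obey their defining identity off flat ground", {
  stk <- test_stack()
  tanb <- tan(stk$beta$values * pi / 180)
  sel <- tanb > 1e-3
  lhs <- exp(stk$TWI$values[sel]) * stk$SPI$values[sel]
  expect_equal(lhs, stk$As$values[sel]^2, tolerance = 1e-10)
  # flat-cell limit: TWI capped via the tan floor, SPI exactly 0
  flatish <- flat_dem(16, 16)
  flatish$values[8, 8] <- 100  # keep it fully flat
  fl <- flow_and_indices(flatish)
  expect_true(all(fl$SPI$values == 0))
  expect_equal(fl$TWI$values, log(fl$As$values / 1e-3), tolerance = 1e-12)
})

test_that("terrain covariates are invariant to a constant elevation shift", {
  dem <- generate_dem(c(24, 24), 20, seed = 5)
  up <- raster_grid(dem$values + 500, dem$xll, dem$yll, dem$cellsize)
  s1 <- terrain_stack(dem); s2 <- terrain_stack(up)
  for (nm in setdiff(covariate_names(), "Hr"))
    expect_equal(s2[[nm]]$values, s1[[nm]]$values, tolerance = 1e-10,
                 label = nm)
  expect_equal(s2$Hr$values, s1$Hr$values)  # Hr is relative, also unchanged
})

test_that("RPI is 0 on the valley mask, 1 on the ridge mask, in [0,1]", {
  dem <- generate_dem(c(32, 32), 20, seed = 9)
  rp <- rpi(dem)
  v <- rp$RPI$values
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(v[rp$valley & !rp$ridge] == 0))
  expect_true(all(v[rp$ridge & !rp$valley] == 1))
  # midpoint equidistant between a valley line and a ridge line scores 0.5
  g <- flat_dem(9, 9, cs = 1)
  valley <- matrix(FALSE, 9, 9); valley[, 1] <- TRUE
  ridge <- matrix(FALSE, 9, 9); ridge[, 9] <- TRUE
  dv <- soilfertmap:::dist_to_mask(g, valley)
  dr <- soilfertmap:::dist_to_mask(g, ridge)
  expect_equal((dv / (dv + dr))[5, 5], 0.5)
})

test_that("covariate sampling has the full schema and matches grid lookup", {
  stk <- test_stack()
  pts <- random_plots(stk, 10, seed = 3)
  covs <- sample_covariates(stk, pts)
  expect_identical(names(covs), covariate_names())
  idx <- cell_index(stk$dem, pts$x, pts$y)
  expect_equal(covs$beta, stk$beta$values[cbind(idx$row, idx$col)])
  expect_equal(covs$TWI, stk$TWI$values[cbind(idx$row, idx$col)])
  expect_error(sample_covariates(stk, data.frame(x = -1e6, y = 0)),
               "out of grid bounds")
})
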