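test_that("single-property grading matches the survey table rows", {
  expect_equal(single_grade("OM", 35), 2L)    # 30-40 band
  expect_equal(single_grade("AN", 10), 8L)    # below 20: very low
  expect_equal(single_grade("TK", 30), 1L)    # above 25: very high
  # shared boundaries fall into the lower grade (upper-closed intervals)
  expect_equal(single_grade("OM", 40), 2L)
  expect_equal(single_grade("OM", 40.0001), 1L)
  expect_equal(single_grade("pH", 8.3), 2L)
  # properties with blank low rows bottom out at their lowest defined grade
  expect_equal(single_grade("TN", 0.3), 7L)
  expect_equal(single_grade("TP", 0.05), 6L)
  expect_error(single_grade("XX", 1), "no grading row")
  expect_error(single_grade("OM", NaN), "finite")
})

test_that("Fi scores follow the piecewise form and stay continuous", {
  p <- default_fi_params()
  expect_equal(fi_score(0.75, p$TN), 1)
  expect_equal(fi_score(2.5, p$TN), 3)
  expect_equal(fi_score(1.125, p$TN), 1.5)
  expect_equal(fi_score(7.0, p$pH), 3)     # best-case alkalinity
  expect_equal(fi_score(8.0, p$pH), 2)
  expect_equal(fi_score(9.0, p$pH), 1)
  expect_equal(fi_score(10.0, p$pH), 0.9)  # xa/ci above xa
  # continuity at every threshold, both directions
  eps <- 1e-9
  for (nm in names(p)) {
    for (thr in c(p[[nm]]$xa, p[[nm]]$xc, p[[nm]]$xp)) {
      expect_lt(abs(fi_score(thr + eps, p[[nm]]) - fi_score(thr, p[[nm]])),
                1e-6, label = paste(nm, thr))
    }
  }
  # monotone nondecreasing in ci for increasing direction, bounded (0, 3]
  ci <- seq(0.05, 5, by = 0.01)
  f <- fi_score(ci, p$TN)
  expect_true(all(diff(f) >= -1e-12))
  expect_true(all(f > 0 & f <= 3))
  expect_error(fi_score(-1, p$TN), "> 0")
  expect_error(fi_score(1, list(xa = 2, xc = 1, xp = 3)), "xa < xc < xp")
})

test_that("the improved Nemerow index matches closed forms", {
  expect_warning(r <- nemerow_F(rep(1, 8)), "2.70")
  expect_equal(r$F, 0.875)
  expect_identical(r$class, "IV")
  # symmetric case: all components equal c gives c * 7/8
  for (cv in c(0.5, 1.7, 3))
    expect_equal(nemerow_F(rep(cv, 8), warn_unreachable = FALSE)$F,
                 cv * 7 / 8)
  r2 <- nemerow_F(c(rep(2, 7), 1), warn_unreachable = FALSE)
  expect_equal(r2$F, sqrt((1.875^2 + 1^2) / 2) * 0.875, tolerance = 1e-12)
  expect_equal(r2$F, 1.3148, tolerance = 1e-4)
  expect_error(nemerow_F(numeric(0)), "empty")
  expect_error(nemerow_F(c(1, 3.5)), "\\(0, 3\\]")
})

test_that("minimum-based F is dominated by the classical maximum form", {
  set.seed(41)
  for (i in 1:1000) {
    fi <- runif(8, 0.01, 3)
    f_min <- nemerow_F(fi, warn_unreachable = FALSE)$F
    f_max <- sqrt((mean(fi)^2 + max(fi)^2) / 2) * 7 / 8
    expect_gte(f_max, f_min)
  }
})

test_that("F classification is right-continuous at the printed bounds", {
  expect_identical(classify_F(2.70), "I")
  expect_identical(classify_F(2.699999), "II")
  expect_identical(classify_F(1.80), "II")
  expect_identical(classify_F(0.90), "III")
  expect_identical(classify_F(0.89), "IV")
})

test_that("fertility surfaces compose the per-cell pieces correctly", {
  p <- default_fi_params()
  props <- names(p)
  mk <- function(val) raster_grid(matrix(val, 4, 4), cellsize = 10)
  # every property at its xa: all Fi = 1, F = 0.875, all barren
  at_xa <- lapply(props, function(nm) mk(p[[nm]]$xa))
  names(at_xa) <- props
  fr <- fertility_surface(at_xa)
  expect_true(all(abs(fr$F$values - 0.875) < 1e-12))
  expect_identical(unname(fr$fractions), 1)
  expect_identical(names(fr$fractions), "IV")
  # one property at its best: F rises but stays governed by Fmin = 1
  best <- at_xa
  best$OM <- mk(p$OM$xp + 1)
  fr2 <- fertility_surface(best)
  f_expect <- sqrt((mean(c(rep(1, 7), 3))^2 + 1^2) / 2) * 7 / 8
  expect_true(all(abs(fr2$F$values - f_expect) < 1e-12))
  # nodata propagates
  holed <- at_xa
  holed$TN$values[2, 2] <- NA
  fr3 <- fertility_surface(holed)
  expect_true(is.na(fr3$F$values[2, 2]))
  expect_identical(sum(is.na(fr3$F$values)), 1L)
  # misaligned grids rejected
  bad <- at_xa
  bad$TN <- raster_grid(matrix(1, 5, 4), cellsize = 10)
  expect_error(fertility_surface(bad), "not aligned")
  # non-positive cells floored with a warning
  neg <- at_xa
  neg$AP$values[1, 1] <- -2
  expect_warning(fertility_surface(neg), "floored")
})

test_that("area fractions count classes exactly and sum to one", {
  cls <- matrix(c("I", "I", "IV"), 1)
  fr <- area_fractions(cls)
  expect_equal(unname(fr["I"]), 2 / 3)
  expect_equal(unname(fr["IV"]), 1 / 3)
  g10 <- c("I", "II", "II", "III", "III", "III", "IV", "IV", "IV", "IV")
  fr10 <- area_fractions(g10)
  expect_equal(unname(fr10), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(sum(fr10), 1)
  expect_identical(unname(area_fractions(rep("III", 7))), 1)
  expect_error(area_fractions(c(NA, NA)), "nodata")
})
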