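test_that("degenerate and symmetric OK configurations behave analytically", {
  vm <- variogram_model("spherical", 0, 1, 50)
  # single sample: its value everywhere
  one <- data.frame(x = 0, y = 0, value = 7)
  s <- ok_predict(one, vm, data.frame(x = c(-5, 3, 40), y = c(0, 2, 9)))
  expect_equal(s$pred, rep(7, 3))
  # two samples equidistant from the target: equal weights, mean prediction
  two <- data.frame(x = c(-10, 10), y = c(0, 0), value = c(2, 6))
  s2 <- ok_predict(two, vm, data.frame(x = 0, y = 0), keep_weights = TRUE)
  expect_equal(as.vector(s2$weights), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(s2$pred, 4)
})

test_that("OK weights equal an independently assembled dense solve", {
  vm <- variogram_model("exponential", 0.1, 0.9, 30)
  set.seed(6)
  x <- runif(5, 0, 50); y <- runif(5, 0, 50); v <- rnorm(5, 10)
  tx <- 25; ty <- 25
  s <- ok_predict(data.frame(x = x, y = y, value = v), vm,
                  data.frame(x = tx, y = ty), keep_weights = TRUE)
  # oracle: assemble the 6x6 bordered system and solve densely
  G <- matrix(0, 6, 6)
  for (i in 1:5) for (j in 1:5)
    G[i, j] <- vgm_eval(vm, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  G[6, 1:5] <- 1; G[1:5, 6] <- 1
  b <- c(vapply(1:5, function(i)
    vgm_eval(vm, sqrt((x[i] - tx)^2 + (y[i] - ty)^2)), 0), 1)
  sol <- solve(G, b)
  expect_lt(max(abs(as.vector(s$weights) - sol[1:5])), 1e-8)
  expect_lt(abs(s$pred - sum(sol[1:5] * v)), 1e-8)
})

test_that("OK is exact at samples with zero nugget and weights sum to one", {
  vm <- variogram_model("spherical", 0, 1.5, 200)
  stk <- test_stack()
  tab <- random_plots(stk, 25, seed = 12)
  tab$value <- rnorm(25, 5)
  at_samples <- ok_predict(tab, vm, tab[, c("x", "y")])
  expect_lt(max(abs(at_samples$pred - tab$value)), 1e-8)
  grid_surf <- ok_predict(tab, vm, stk$dem, keep_weights = TRUE)
  expect_lt(max(abs(colSums(grid_surf$weights) - 1)), 1e-8)
  expect_true(all(grid_surf$var$values >= 0))
})

test_that("increasing nugget fraction drives weights toward 1/n", {
  set.seed(7)
  x <- runif(6, 0, 100); y <- runif(6, 0, 100)
  tab <- data.frame(x = x, y = y, value = rnorm(6))
  tgt <- data.frame(x = 50, y = 50)
  spread <- function(nugfrac) {
    vm <- variogram_model("spherical", nugfrac, 1 - nugfrac, 60)
    w <- ok_predict(tab, vm, tgt, keep_weights = TRUE)$weights
    max(abs(w - 1 / 6))
  }
  sp <- vapply(c(0.01, 0.5, 0.99, 0.999999), spread, 0)
  expect_true(all(diff(sp) < 0))
  expect_lt(sp[4], 1e-4)
})

test_that("duplicate sample coordinates are averaged with a warning", {
  vm <- variogram_model("spherical", 0, 1, 50)
  tab <- data.frame(x = c(0, 0, 10), y = c(0, 0, 0), value = c(2, 4, 9))
  expect_warning(s <- ok_predict(tab, vm, data.frame(x = 0, y = 0)),
                 "averaged")
  expect_equal(s$pred, 3)  # exact at the (averaged) sample with C0 = 0
})

test_that("stepwise regression recovers an exact linear signal", {
  stk <- test_stack()
  tab <- random_plots(stk, 40, seed = 13)
  covs <- sample_covariates(stk, tab)[, c("beta", "Hr", "TWI", "RPI", "M")]
  y <- 3 + 2 * covs$beta
  dm <- stepwise_drift(covs, y)
  expect_identical(dm$selected, "beta")
  expect_equal(unname(dm$coefficients["(Intercept)"]), 3, tolerance = 1e-8)
  expect_equal(unname(dm$coefficients[["beta"]]), 2, tolerance = 1e-8)
  expect_equal(dm$r_squared, 1, tolerance = 1e-10)
})

test_that("identical covariate columns are never co-selected", {
  stk <- test_stack()
  tab <- random_plots(stk, 40, seed = 14)
  covs <- sample_covariates(stk, tab)[, c("beta", "Hr")]
  covs$beta_copy <- covs$beta
  set.seed(15)
  y <- 1 + 0.5 * covs$beta + rnorm(40, 0, 0.2)
  dm <- stepwise_drift(covs, y)
  expect_lte(sum(c("beta", "beta_copy") %in% dm$selected), 1)
  if (length(dm$selected) > 1)
    expect_true(all(dm$vif <= dm$vif_max))
})

test_that("pure-noise responses rarely admit covariates", {
  stk <- test_stack()
  tab <- random_plots(stk, 50, seed = 16)
  covs <- sample_covariates(stk, tab)
  counts <- vapply(1:20, function(s) {
    set.seed(700 + s)
    length(stepwise_drift(covs, rnorm(50))$selected)
  }, 0)
  # alpha = 0.05 over 12 candidates: mean admissions should stay near
  # alpha * candidates; generous factor 2.5 for selection bias
  expect_lt(mean(counts), 0.05 * ncol(covs) * 2.5)
})

test_that("PRESS equals explicit leave-one-out refitting", {
  stk <- test_stack()
  tab <- random_plots(stk, 30, seed = 17)
  covs <- sample_covariates(stk, tab)[, c("beta", "Hr", "RPI")]
  set.seed(18)
  y <- 2 + 0.4 * covs$beta - 0.01 * covs$Hr + rnorm(30, 0, 0.3)
  dm <- stepwise_drift(covs, y)
  X <- covs[dm$selected]
  press <- 0
  for (i in seq_len(30)) {
    f <- stats::lm(y[-i] ~ ., data = X[-i, , drop = FALSE])
    press <- press + (y[i] - stats::predict(f, X[i, , drop = FALSE]))^2
  }
  expect_equal(dm$press, unname(press), tolerance = 1e-8)
})

test_that("VIF matches the car reference on a fitted model", {
  skip_if_not_installed("car")
  stk <- test_stack()
  tab <- random_plots(stk, 40, seed = 19)
  covs <- sample_covariates(stk, tab)[, c("beta", "Hr", "TWI")]
  set.seed(20)
  y <- 1 + 0.2 * covs$beta + 0.01 * covs$Hr + rnorm(40, 0, 0.5)
  fit <- stats::lm(y ~ ., data = covs)
  expect_equal(unname(soilfertmap:::vif_of(as.matrix(covs))),
               unname(car::vif(fit)), tolerance = 1e-8)
})

test_that("RK reduces to its parts in the degenerate directions", {
  stk <- test_stack()
  tab <- random_plots(stk, 35, seed = 21)
  covs <- sample_covariates(stk, tab)
  # residuals identically zero: RK returns the drift surface exactly
  tab$value <- 4 + 0.3 * covs$beta
  s <- rk_predict(tab, stk, stk$dem)
  expect_equal(s$pred$values, 4 + 0.3 * stk$beta$values, tolerance = 1e-6)
  # no covariate qualifies: RK equals OK under the same residual variogram
  set.seed(22)
  tab$value <- rnorm(35, 10, 1)
  rk <- rk_predict(tab, stk, stk$dem)
  ok <- ok_predict(tab, rk$vmodel, stk$dem)
  if (length(rk$drift_model$selected) == 0)
    expect_lt(max(abs(rk$pred$values - ok$pred$values)), 1e-8)
})

test_that("back-transforms behave on constants and bias-correct on average", {
  vm <- variogram_model("spherical", 0, 0.5, 100)
  stk <- test_stack()
  tab <- random_plots(stk, 20, seed = 23)
  tab$value <- rep(2, 20)
  s <- ok_predict(tab, vm, data.frame(x = 100, y = 100), log_scale = TRUE)
  naive <- back_transform(s, "naive")
  expect_equal(naive$pred, exp(s$pred))
  expect_false(naive$log_scale)
  expect_error(back_transform(naive), "not on the log scale")
  # zero kriging variance: both modes agree
  at_sample <- ok_predict(tab, vm, tab[1, c("x", "y")], log_scale = TRUE)
  expect_equal(back_transform(at_sample, "naive")$pred,
               back_transform(at_sample, "lognormal")$pred, tolerance = 1e-8)
  # lognormal truth: the sigma^2/2 correction shrinks the mean bias
  vm2 <- variogram_model("spherical", 0.05, 0.45, 350)
  biases <- vapply(1:20, function(s) {
    pts <- sample_plots(stk$dem, 60, seed = 800 + s)
    sim <- simulate_samples(stk, pts, c("(Intercept)" = 1), vm2,
                            seed = 900 + s)
    train <- sim[1:40, ]; test <- sim[41:60, ]
    surf <- ok_predict(data.frame(x = train$x, y = train$y,
                                  value = train$value),
                       vm2, data.frame(x = test$x, y = test$y),
                       log_scale = TRUE)
    truth <- exp(test$value)
    c(naive = mean(exp(surf$pred) - truth),
      logn = mean(back_transform(surf, "lognormal")$pred - truth))
  }, c(naive = 0, logn = 0))
  expect_lt(abs(mean(biases["logn", ])), abs(mean(biases["naive", ])))
})
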