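# Ordinary kriging and terrain-drift regression kriging.  Global
# neighbourhood: with ~70 plots per property/layer the full system is solved
# exactly rather than through moving windows.

# average observations sharing (numerically) the same coordinates
average_duplicates <- function(x, y, values, tol = 1e-8) {
  key <- paste(round(x / tol), round(y / tol))
  if (!anyDuplicated(key)) return(data.frame(x = x, y = y, value = values))
  warning("duplicate sample coordinates averaged before kriging")
  agg <- stats::aggregate(data.frame(x = x, y = y, value = values),
                          by = list(key = key), FUN = mean)
  data.frame(x = agg$x, y = agg$y, value = agg$value)
}

# assemble and solve the OK system for all targets at once.
# returns prediction, kriging variance, and (optionally) the weight matrix.
ok_solve <- function(sx, sy, sv, vmodel, tx, ty, keep_weights = FALSE) {
  n <- length(sv)
  if (n == 1L) {
    m <- length(tx)
    return(list(pred = rep(sv, m),
                var = rep(vmodel$nugget + vmodel$psill, m),
                weights = if (keep_weights) matrix(1, 1, m)))
  }
  if (vmodel$nugget + vmodel$psill == 0) {
    # degenerate zero-sill model (e.g. constant residual field): the BLUP
    # collapses to the sample mean with zero kriging variance
    m <- length(tx)
    return(list(pred = rep(mean(sv), m), var = rep(0, m),
                weights = if (keep_weights) matrix(1 / n, n, m)))
  }
  d <- sqrt(outer(sx, sx, "-")^2 + outer(sy, sy, "-")^2)
  Gam <- rbind(cbind(vgm_eval(vmodel, d), 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(sx, tx, "-")^2 + outer(sy, ty, "-")^2)
  B <- rbind(vgm_eval(vmodel, d0), 1)
  sol <- tryCatch(solve(Gam, B), error = function(e) e)
  if (inherits(sol, "error")) {
    # ill-conditioned structure (e.g. a gaussian model with range far
    # beyond the domain): retry once with a tiny nugget jitter
    jit <- 1e-8 * (vmodel$nugget + vmodel$psill)
    Gj <- Gam
    Gj[seq_len(n), seq_len(n)] <- Gj[seq_len(n), seq_len(n)] +
      jit * (1 - diag(n))
    sol <- tryCatch(solve(Gj, B + jit * (B != 0 & row(B) <= n)),
                    error = function(e)
                      stop("singular kriging system: ", conditionMessage(e)))
  }
  w <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  list(pred = drop(crossprod(w, sv)),
       var = pmax(colSums(w * B[seq_len(n), , drop = FALSE]) + mu, 0),
       weights = if (keep_weights) w)
}

target_xy <- function(targets) {
  if (inherits(targets, "raster_grid")) {
    cc <- grid_coords(targets)
    list(x = cc$x, y = cc$y, grid = targets)
  } else list(x = targets$x, y = targets$y, grid = NULL)
}

as_surface <- function(pred, var, tgt, method, log_scale = FALSE,
                       extra = list()) {
  if (!is.null(tgt$grid)) {
    g <- tgt$grid
    nr <- nrow(g$values)
    shape <- function(v) raster_grid(matrix(v, nr), g$xll, g$yll, g$cellsize)
    pred <- shape(pred); var <- shape(var)
  }
  structure(c(list(pred = pred, var = var, method = method,
                   log_scale = log_scale), extra),
            class = "prediction_surface")
}

#' @export
print.prediction_surface <- function(x, ...) {
  cat(sprintf("prediction_surface (%s%s)\n", x$method,
              if (x$log_scale) ", log scale" else ""))
  invisible(x)
}

surface_values <- function(s) {
  if (inherits(s$pred, "raster_grid")) s$pred$values else s$pred
}

#' Ordinary kriging prediction
#'
#' Solves the ordinary-kriging system (weights constrained to sum to one)
#' built from the semivariogram model, for every target location. With a
#' zero nugget the predictor interpolates the observations exactly.
#'
#' @param table data.frame with columns x, y, value; duplicate coordinates
#'   are averaged with a warning.
#' @param vmodel a `variogram_model`.
#' @param targets a data.frame with x, y or a `raster_grid` template (all
#'   cell centres predicted).
#' @param keep_weights keep the n x m kriging weight matrix (for
#'   diagnostics; memory heavy on large grids).
#' @param log_scale mark the resulting surface as being on the natural-log
#'   scale (for later [back_transform()]).
#' @return a `prediction_surface` with prediction and kriging variance.
#' @export
ok_predict <- function(table, vmodel, targets, keep_weights = FALSE,
                       log_scale = FALSE) {
  tab <- average_duplicates(table$x, table$y, table$value)
  tgt <- target_xy(targets)
  sol <- ok_solve(tab$x, tab$y, tab$value, vmodel, tgt$x, tgt$y,
                  keep_weights)
  as_surface(sol$pred, sol$var, tgt, "OK", log_scale,
             extra = list(weights = sol$weights, vmodel = vmodel))
}

# variance inflation factors from the inverse correlation matrix of the
# retained columns (1 for a single column)
vif_of <- function(X) {
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  R <- stats::cor(X)
  stats::setNames(diag(solve(R)), colnames(X))
}

#' Forward-backward stepwise drift regression
#'
#' Forward selection / backward elimination on t-test p-values at a common
#' entry and stay level, with a variance-inflation-factor cap as the
#' collinearity guard: a candidate whose entry pushes any VIF over the cap
#' (including exact duplicates of a retained column) is not admitted.
#' Reports coefficients, R^2, VIF and PRESS (the sum of squared
#' leave-one-out residuals).
#'
#' @param covariates data.frame of candidate covariate columns.
#' @param values response vector.
#' @param alpha significance level for entry and stay (default 0.05).
#' @param vif_max VIF cap for retained covariates (default 10).
#' @return object of class `drift_model`: selected names, coefficients
#'   (with intercept), residuals, fitted values, R^2, PRESS, VIF.
#' @export
stepwise_drift <- function(covariates, values, alpha = 0.05, vif_max = 10) {
  covariates <- as.data.frame(covariates)
  cand <- names(covariates)
  usable <- vapply(covariates, function(v)
    all(is.finite(v)) && stats::sd(v) > 0, TRUE)
  cand <- cand[usable]
  dat <- cbind(covariates, .y = values)
  selected <- character()
  refit <- function(sel) {
    f <- if (length(sel))
      stats::reformulate(sprintf("`%s`", sel), response = ".y")
    else .y ~ 1
    stats::lm(f, data = dat)
  }
  tiny <- 1e-8 * max(stats::sd(values), .Machine$double.eps)
  repeat {
    changed <- FALSE
    # forward: best admissible candidate below alpha -- unless the current
    # model already fits to numerical precision (p-values computed against
    # machine-epsilon residuals are meaningless)
    pool <- setdiff(cand, selected)
    if (length(pool) && stats::sd(stats::residuals(refit(selected))) > tiny) {
      pvals <- rep(NA_real_, length(pool))
      for (j in seq_along(pool)) {
        trial <- c(selected, pool[j])
        fit <- refit(trial)
        co <- suppressWarnings(summary(fit))$coefficients
        if (anyNA(stats::coef(fit)) || nrow(co) != length(trial) + 1) next
        if (length(trial) > 1 &&
            any(vif_of(as.matrix(dat[trial])) > vif_max)) next
        pvals[j] <- co[nrow(co), 4]
      }
      if (any(!is.na(pvals)) && min(pvals, na.rm = TRUE) < alpha) {
        selected <- c(selected, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward: drop the worst retained term above alpha
    if (length(selected)) {
      co <- suppressWarnings(summary(refit(selected)))$coefficients
      p <- co[-1, 4]
      # zero coefficient with zero SE (exact fit leftovers) is vacuous
      p[is.nan(p)] <- 1
      if (max(p) >= alpha) {
        selected <- setdiff(selected, selected[which.max(p)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- refit(selected)
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  res <- stats::residuals(fit)
  structure(list(
    selected = selected,
    coefficients = stats::coef(fit),
    residuals = res,
    fitted = stats::fitted(fit),
    r_squared = suppressWarnings(summary(fit))$r.squared,
    press = sum((res / (1 - h))^2),
    vif = if (length(selected) > 1) vif_of(as.matrix(dat[selected]))
          else stats::setNames(rep(1, length(selected)), selected),
    alpha = alpha, vif_max = vif_max, fit = fit),
    class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat("drift_model:",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(intercept only)", "\n")
  cat(sprintf("  R^2 = %.4f  PRESS = %.4g\n", x$r_squared, x$press))
  invisible(x)
}

# evaluate a drift model on a covariate data.frame
drift_predict <- function(dm, covariates) {
  b <- dm$coefficients
  out <- rep(unname(b["(Intercept)"]), nrow(covariates))
  for (nm in dm$selected) out <- out + b[[nm]] * covariates[[nm]]
  out
}

#' Regression-kriging prediction
#'
#' Fits a stepwise terrain drift at the sample locations, models the
#' semivariogram of its residuals (auto model selection), kriges the
#' residuals to the targets and adds the drift evaluated there:
#' prediction = drift + kriged residual. With an intercept-only drift this
#' reduces to ordinary kriging.
#'
#' @inheritParams ok_predict
#' @param stack a `terrain_stack` providing covariates at samples and
#'   targets.
#' @param alpha,vif_max stepwise entry/stay level and VIF cap.
#' @param n_lags,max_dist empirical-variogram binning for the residuals.
#' @param resid_vmodel optional `variogram_model` for the residuals; fitted
#'   automatically when NULL.
#' @return a `prediction_surface` (method "RK") carrying the drift model and
#'   residual variogram.
#' @export
rk_predict <- function(table, stack, targets, alpha = 0.05, vif_max = 10,
                       n_lags = 12, max_dist = NULL, resid_vmodel = NULL,
                       log_scale = FALSE) {
  tab <- average_duplicates(table$x, table$y, table$value)
  covs <- sample_covariates(stack, tab)
  dm <- stepwise_drift(covs, tab$value, alpha, vif_max)
  res <- dm$residuals
  if (is.null(resid_vmodel)) {
    if (stats::sd(res) <= 1e-10 * max(stats::sd(tab$value), 1e-12)) {
      # the drift explains the data to machine precision; a degenerate
      # zero-sill model short-circuits the residual kriging to the mean
      resid_vmodel <- variogram_model("spherical", 0, 0, 1)
    } else {
      emp <- empirical_variogram(tab$x, tab$y, res, n_lags, max_dist)
      resid_vmodel <- fit_variogram(emp, "auto")
    }
  }
  tgt <- target_xy(targets)
  tcovs <- sample_covariates(stack, data.frame(x = tgt$x, y = tgt$y))
  dr <- drift_predict(dm, tcovs)
  sol <- ok_solve(tab$x, tab$y, res, resid_vmodel, tgt$x, tgt$y)
  as_surface(dr + sol$pred, sol$var, tgt, "RK", log_scale,
             extra = list(drift_model = dm, vmodel = resid_vmodel))
}

#' Back-transform a log-scale prediction surface
#'
#' naive: exp(prediction); lognormal: exp(prediction + kriging variance / 2),
#' the standard lognormal-kriging bias correction.
#'
#' @param surface a `prediction_surface` built on the log scale.
#' @param mode "naive" (default) or "lognormal".
#' @return the surface on the measurement scale (`log_scale = FALSE`,
#'   `back_transform` mode recorded).
#' @export
back_transform <- function(surface, mode = c("naive", "lognormal")) {
  mode <- match.arg(mode)
  if (!isTRUE(surface$log_scale))
    stop("surface is not on the log scale; nothing to back-transform")
  grab <- function(s) if (inherits(s, "raster_grid")) s$values else s
  pred <- grab(surface$pred); var <- grab(surface$var)
  out <- if (mode == "naive") exp(pred) else exp(pred + var / 2)
  if (inherits(surface$pred, "raster_grid"))
    out <- raster_grid(out, surface$pred$xll, surface$pred$yll,
                       surface$pred$cellsize)
  surface$pred <- out
  surface$log_scale <- FALSE
  surface$back_transform <- mode
  surface
}
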