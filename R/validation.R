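# Leave-one-out cross-validation, interpolation error statistics and
# per-property method selection between ordinary and regression kriging.

#' Interpolation error statistics
#'
#' ME = mean(observed - predicted) (bias, ~0 for unbiased predictors);
#' MRE = mean(|observed - predicted| / observed), reported as a fraction by
#' default; RMSE = root mean squared error. Pairs with observed value 0 are
#' skipped in MRE with a warning.
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @param percent report MRE in percent instead of as a fraction.
#' @return object of class `error_stats`: me, mre, rmse, m, and the paired
#'   vectors.
#' @export
error_stats <- function(observed, predicted, percent = FALSE) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 1) stop("need at least one pair")
  err <- observed - predicted
  nz <- observed != 0
  if (!all(nz)) warning("observed values of 0 skipped in MRE")
  mre <- mean(abs(err[nz]) / observed[nz])
  structure(list(me = mean(err),
                 mre = if (percent) 100 * mre else mre,
                 rmse = sqrt(mean(err^2)),
                 m = length(observed),
                 observed = observed, predicted = predicted,
                 percent = percent),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("error_stats (m = %d): ME = %.4f  MRE = %.4f%s  RMSE = %.4f\n",
              x$m, x$me, x$mre, if (x$percent) "%" else "", x$rmse))
  invisible(x)
}

# one held-out prediction with the full fit (transform decision, variogram,
# drift) redone on the training points only
loocv_one <- function(i, table, method, stack, n_lags, max_dist,
                      transform, back) {
  train <- table[-i, , drop = FALSE]
  target <- table[i, c("x", "y"), drop = FALSE]
  td <- if (transform) transform_decision(train$value)
        else list(scale = "raw", values = train$value)
  wtab <- data.frame(x = train$x, y = train$y, value = td$values)
  log_scale <- td$scale == "log"
  emp <- empirical_variogram(wtab$x, wtab$y, wtab$value, n_lags, max_dist)
  surf <- if (method == "OK") {
    vm <- fit_variogram(emp, "auto")
    ok_predict(wtab, vm, target, log_scale = log_scale)
  } else {
    rk_predict(wtab, stack, target, n_lags = n_lags, max_dist = max_dist,
               log_scale = log_scale)
  }
  if (log_scale) surf <- back_transform(surf, back)
  surface_values(surf)[1]
}

#' Leave-one-out cross-validation of a kriging method
#'
#' For each point the entire fit -- log-transform decision, empirical
#' variogram and model fit, and (for RK) the stepwise drift and residual
#' variogram -- is redone without that point and the point is predicted.
#' Predictions are returned on the original measurement scale, in input
#' order. A failure at one held-out point yields NA there (with a warning)
#' rather than aborting the whole validation.
#'
#' @param table data.frame with x, y, value.
#' @param method "OK" or "RK".
#' @param stack a `terrain_stack` (required for RK).
#' @param n_lags,max_dist empirical-variogram binning.
#' @param transform apply the skewness > 1 log-transform rule per fold.
#' @param back back-transform mode for log-scale fits.
#' @return numeric vector of held-out predictions.
#' @export
loocv <- function(table, method = c("OK", "RK"), stack = NULL, n_lags = 12,
                  max_dist = NULL, transform = TRUE, back = "naive") {
  method <- match.arg(method)
  n <- nrow(table)
  if (n < 5) stop("need at least 5 points for leave-one-out validation")
  if (method == "RK" && is.null(stack))
    stop("RK validation needs a terrain_stack")
  vapply(seq_len(n), function(i) {
    tryCatch(
      suppressWarnings(loocv_one(i, table, method, stack, n_lags, max_dist,
                                 transform, back)),
      error = function(e) {
        warning("held-out point ", i, " failed: ", conditionMessage(e))
        NA_real_
      })
  }, 0)
}

#' Choose between ordinary and regression kriging
#'
#' Preferred method = lower RMSE; ties broken by lower MRE, then lower |ME|,
#' then OK (parsimony).
#'
#' @param ok_stats,rk_stats `error_stats` for the two methods.
#' @param property,layer optional labels carried into the report.
#' @return object of class `method_report` with `preferred` ("OK" or "RK")
#'   and the rule that decided.
#' @export
select_method <- function(ok_stats, rk_stats, property = NA, layer = NA) {
  pick <- if (ok_stats$rmse != rk_stats$rmse) {
    list(p = if (rk_stats$rmse < ok_stats$rmse) "RK" else "OK",
         rule = "lower RMSE")
  } else if (ok_stats$mre != rk_stats$mre) {
    list(p = if (rk_stats$mre < ok_stats$mre) "RK" else "OK",
         rule = "RMSE tie: lower MRE")
  } else if (abs(ok_stats$me) != abs(rk_stats$me)) {
    list(p = if (abs(rk_stats$me) < abs(ok_stats$me)) "RK" else "OK",
         rule = "RMSE/MRE tie: lower |ME|")
  } else list(p = "OK", rule = "full tie: OK by parsimony")
  structure(list(property = property, layer = layer,
                 ok = ok_stats, rk = rk_stats,
                 preferred = pick$p, rule = pick$rule),
            class = "method_report")
}

#' @export
print.method_report <- function(x, ...) {
  cat(sprintf("method_report %s %s: preferred %s (%s)\n",
              x$property, x$layer,
              if (x$preferred == "RK") "regression kriging"
              else "ordinary kriging", x$rule))
  invisible(x)
}

#' Descriptive statistics of a sample
#'
#' Max, min, mean, sample SD, CV (percent), adjusted Fisher-Pearson skewness
#' and excess kurtosis, on the raw scale and (when all values are positive)
#' the natural-log scale. A constant vector gets skewness/kurtosis 0 with
#' `degenerate = TRUE`.
#'
#' @param values numeric vector, n >= 4.
#' @return object of class `summary_stats` (a one-row data.frame per scale).
#' @export
summary_stats <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  one <- function(v) {
    s <- stats::sd(v)
    degen <- s == 0
    data.frame(max = max(v), min = min(v), mean = mean(v), sd = s,
               cv = if (mean(v) != 0) 100 * s / mean(v) else NA_real_,
               skewness = if (degen) 0 else e1071::skewness(v, type = 2),
               kurtosis = if (degen) 0 else e1071::kurtosis(v, type = 2),
               degenerate = degen)
  }
  out <- list(raw = one(values),
              log = if (min(values) > 0) one(log(values)) else NULL)
  structure(out, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("summary_stats (raw):\n"); print(x$raw, row.names = FALSE)
  if (!is.null(x$log)) { cat("log scale:\n"); print(x$log, row.names = FALSE) }
  invisible(x)
}
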