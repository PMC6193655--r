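#' Variogram model object
#'
#' Bundles a permissible semivariogram model: kind, nugget C0, partial sill C
#' and range a, together with the nugget-to-sill ratio and its spatial
#' dependency class.
#'
#' @param kind one of "spherical", "exponential", "gaussian", "linear".
#' @param nugget nugget variance C0 (>= 0).
#' @param psill partial sill C (>= 0); total sill is C0 + C.
#' @param range correlation length a (> 0).
#' @param rss optional weighted residual sum of squares from fitting.
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(kind = c("spherical", "exponential", "gaussian",
                                     "linear"),
                            nugget, psill, range, rss = NA_real_) {
  kind <- match.arg(kind)
  if (nugget < 0 || psill < 0) stop("nugget and partial sill must be >= 0")
  if (range <= 0) stop("range must be > 0")
  ns <- if (nugget + psill > 0) nugget / (nugget + psill) else NA_real_
  structure(list(kind = kind, nugget = nugget, psill = psill, range = range,
                 ns_ratio = ns,
                 class = if (is.na(ns)) NA_character_ else
                   dependency_class_ratio(ns),
                 rss = rss),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s  C0 = %.4g  C = %.4g  a = %.4g\n",
              x$kind, x$nugget, x$psill, x$range))
  cat(sprintf("  N/S = %.3f (%s dependency)\n", x$ns_ratio, x$class))
  invisible(x)
}

#' Evaluate a semivariogram model
#'
#' Spherical: C0 + C(3h/2a - h^3/2a^3) up to a, sill beyond; exponential:
#' C0 + C(1 - exp(-h/a)); gaussian: C0 + C(1 - exp(-h^2/a^2)); linear:
#' C0 + (C/a) h up to a, sill beyond. gamma(0) = 0 by convention.
#'
#' @param model a `variogram_model`.
#' @param h nonnegative lag distances.
#' @return semivariances gamma(h).
#' @export
vgm_eval <- function(model, h) {
  C0 <- model$nugget; C <- model$psill; a <- model$range
  g <- switch(model$kind,
    spherical   = ifelse(h <= a,
                         C0 + C * (1.5 * h / a - 0.5 * (h / a)^3),
                         C0 + C),
    exponential = C0 + C * (1 - exp(-h / a)),
    gaussian    = C0 + C * (1 - exp(-h^2 / a^2)),
    linear      = C0 + (C / a) * pmin(h, a))
  g[h == 0] <- 0
  g
}

# structured (nugget-free) covariance implied by the model; used by the
# field simulator.  Linear models have no valid covariance.
vgm_cov <- function(model, h) {
  C <- model$psill; a <- model$range
  switch(model$kind,
    spherical   = ifelse(h <= a, C * (1 - 1.5 * h / a + 0.5 * (h / a)^3), 0),
    exponential = C * exp(-h / a),
    gaussian    = C * exp(-h^2 / a^2),
    linear      = stop("linear variogram model has no positive-definite ",
                       "covariance; cannot simulate from it"))
}

#' Decide whether to log-transform a sample
#'
#' Computes the adjusted Fisher-Pearson sample skewness and applies a natural
#' log transform when skewness exceeds 1.0 and all values are strictly
#' positive. Skewness of exactly 1.0 stays raw.
#'
#' @param values numeric vector, n >= 4.
#' @return list with `scale` ("raw" or "log"), `values` (transformed when
#'   log), and `skewness` of the raw data.
#' @export
transform_decision <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  sk <- e1071::skewness(values, type = 2)
  if (sk > 1.0) {
    if (min(values) > 0)
      return(list(scale = "log", values = log(values), skewness = sk))
    warning("skewness > 1 but nonpositive values present; staying on raw scale")
  }
  list(scale = "raw", values = values, skewness = sk)
}

#' Empirical semivariogram
#'
#' Bins point pairs by separation distance and computes the classical
#' estimator gamma(h) = sum of squared differences over 2 N(h) per bin.
#' Empty bins are dropped.
#'
#' @param x,y point coordinates (map units).
#' @param values observed values at the points.
#' @param n_lags number of equal-width lag bins (>= 2; default 12).
#' @param max_dist maximum pair separation considered; default half the
#'   maximum pairwise distance.
#' @return object of class `empirical_variogram`: data.frame with lag-centre
#'   `h`, mean pair separation `dist`, semivariance `gamma`, pair count
#'   `np`. Model fitting evaluates candidate curves at `dist` (the centre
#'   of mass of each bin), not the nominal bin centre.
#' @export
empirical_variogram <- function(x, y, values, n_lags = 12, max_dist = NULL) {
  n <- length(values)
  if (n < 2) stop("need at least 2 points")
  if (n_lags < 2) stop("n_lags must be >= 2")
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  d <- sqrt(dx^2 + dy^2)
  dv2 <- outer(values, values, "-")^2
  iu <- upper.tri(d)
  d <- d[iu]; dv2 <- dv2[iu]
  if (is.null(max_dist)) max_dist <- max(d) / 2
  if (max_dist > max(d)) stop("max_dist exceeds the maximum pairwise distance")
  keep <- d > 0 & d <= max_dist
  d <- d[keep]; dv2 <- dv2[keep]
  width <- max_dist / n_lags
  bin <- pmin(ceiling(d / width), n_lags)
  np <- tabulate(bin, nbins = n_lags)
  gsum <- vapply(seq_len(n_lags), function(b) sum(dv2[bin == b]), 0)
  dsum <- vapply(seq_len(n_lags), function(b) sum(d[bin == b]), 0)
  keep <- np > 0
  out <- data.frame(h = (seq_len(n_lags) - 0.5)[keep] * width,
                    dist = dsum[keep] / np[keep],
                    gamma = gsum[keep] / (2 * np[keep]),
                    np = np[keep])
  structure(out, class = c("empirical_variogram", "data.frame"),
            max_dist = max_dist, lag_width = width)
}

# one model kind fitted to an empirical variogram by weighted nonlinear
# least squares (weights = pair counts, or Cressie np/gamma_model^2 style)
fit_one_kind <- function(emp, kind, weights = c("cressie", "np")) {
  weights <- match.arg(weights)
  h <- if (!is.null(emp$dist)) emp$dist else emp$h
  g <- emp$gamma; w <- emp$np
  sill0 <- max(g); a0 <- max(h) / 2
  if (kind == "linear") {
    # gamma = C0 + b h over observed lags; range pinned at the longest lag
    fit <- stats::lm(g ~ h, weights = w)
    C0 <- max(0, unname(stats::coef(fit)[1]))
    b <- max(0, unname(stats::coef(fit)[2]))
    a <- max(h)
    pred <- C0 + b * pmin(h, a)
    rss <- sum(w * (g - pred)^2)
    return(variogram_model("linear", C0, b * a, a, rss = rss))
  }
  form <- switch(kind,
    spherical   = g ~ C0 + C * ifelse(h <= a, 1.5 * h / a - 0.5 * (h / a)^3, 1),
    exponential = g ~ C0 + C * (1 - exp(-h / a)),
    gaussian    = g ~ C0 + C * (1 - exp(-h^2 / a^2)))
  dat <- data.frame(h = h, g = g)
  do_fit <- function(w) try(suppressWarnings(minpack.lm::nlsLM(
    form, data = dat, weights = w,
    start = list(C0 = 0.1 * sill0 + 1e-10, C = 0.9 * sill0 + 1e-10, a = a0),
    lower = c(0, 0, 1e-8 * max(h)), upper = c(Inf, Inf, 10 * max(h)),
    control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
  fit <- do_fit(w)
  if (inherits(fit, "try-error")) return(NULL)
  if (weights == "cressie") {
    # Cressie weights depend on the model curve: reweight and refit twice
    for (it in 1:2) {
      w <- emp$np / pmax(stats::predict(fit), 1e-12)^2
      refit <- do_fit(w)
      if (inherits(refit, "try-error")) break
      fit <- refit
    }
  }
  p <- stats::coef(fit)
  pred <- stats::predict(fit)
  rss <- sum(w * (g - pred)^2)
  variogram_model(kind, p[["C0"]], p[["C"]], p[["a"]], rss = rss)
}

#' Fit a variogram model to an empirical variogram
#'
#' Weighted nonlinear least squares with nonnegativity bounds on C0 and C and
#' positivity on a. `kind = "auto"` fits all four permissible models and
#' keeps the one with the lowest weighted residual sum of squares. If no
#' model converges a pure-nugget model is returned with a warning.
#'
#' Weights: "cressie" (default) iteratively reweights by pair count over
#' squared model value, which keeps the short lags -- and hence the nugget
#' -- properly constrained; plain pair-count weights ("np") are available
#' but systematically underestimate the nugget on clustered designs.
#'
#' @param emp an `empirical_variogram` (>= 4 usable lags).
#' @param kind model kind or "auto".
#' @param weights "cressie" (default) or "np" (pair counts).
#' @return a `variogram_model`.
#' @export
fit_variogram <- function(emp, kind = "auto", weights = "cressie") {
  if (nrow(emp) < 4) stop("need at least 4 usable lags")
  kinds <- if (identical(kind, "auto"))
    c("spherical", "exponential", "gaussian", "linear") else kind
  fits <- Filter(Negate(is.null),
                 lapply(kinds, function(k) fit_one_kind(emp, k, weights)))
  if (!length(fits)) {
    warning("no variogram model converged; returning pure-nugget model")
    C0 <- sum(emp$np * emp$gamma) / sum(emp$np)
    return(variogram_model("linear", C0, 0, max(emp$h)))
  }
  fits[[which.min(vapply(fits, function(f) f$rss, 0))]]
}

dependency_class_ratio <- function(ns) {
  if (ns < 0.25) "strong" else if (ns <= 0.75) "moderate" else "weak"
}

#' Spatial dependency class from the nugget-to-sill ratio
#'
#' N/S < 0.25: strong; 0.25-0.75: moderate; > 0.75: weak (the conventional
#' cutoffs for classing spatial dependency of soil properties).
#'
#' @param model a `variogram_model`.
#' @return "strong", "moderate" or "weak".
#' @export
dependency_class <- function(model) {
  if (is.na(model$ns_ratio)) stop("model has zero sill; N/S undefined")
  dependency_class_ratio(model$ns_ratio)
}
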