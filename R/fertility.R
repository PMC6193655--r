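# Soil-fertility assessment: per-property enrichment grades, piecewise
# non-dimensional fertility scores Fi, the improved minimum-based Nemerow
# comprehensive index F, class mapping and area fractions.

#' Default enrichment/paucity grading scheme
#'
#' Grade boundaries per property (grade 1 = very high ... grade 8 = very
#' low), from the provincial second soil survey convention. Intervals are
#' lower-open, upper-closed: a value equal to a printed shared boundary
#' falls in the lower (worse) grade; the top class is a strict ">". TN stops
#' at grade 7 and TP/TK at grade 6 (no lower rows are defined); values below
#' the lowest printed bound take the lowest defined grade.
#'
#' Units: OM, TN, TP, TK in g/kg; AN, AP, AK in mg/kg; pH unitless.
#'
#' @return named list: per property, the descending boundary vector.
#' @export
default_grading <- function() {
  list(OM = c(40, 30, 20, 15, 12, 10, 8),
       TN = c(2.0, 1.5, 1.25, 1.0, 0.75, 0.5),
       TP = c(1, 0.8, 0.6, 0.4, 0.2),
       TK = c(25, 20, 15, 10, 5),
       AN = c(150, 120, 90, 60, 45, 30, 20),
       AP = c(40, 30, 20, 15, 10, 5, 3),
       AK = c(200, 150, 120, 100, 70, 50, 30),
       pH = c(8.3, 8.0, 7.5, 7.0, 6.5, 6.0, 5.7))
}

#' Grade a single-property value
#'
#' @param property property name (one of names(default_grading())).
#' @param value numeric value(s), finite.
#' @param scheme grading scheme (default [default_grading()]).
#' @return integer grade(s), 1 (very high) to at most 8 (very low).
#' @export
single_grade <- function(property, value, scheme = default_grading()) {
  b <- scheme[[property]]
  if (is.null(b)) stop("no grading row for property: ", property)
  if (any(!is.finite(value))) stop("values must be finite")
  # grade = 1 + number of boundaries at or above the value
  vapply(value, function(v) 1L + sum(v <= b), 1L)
}

#' Default Nemerow grading thresholds (xa, xc, xp)
#'
#' Per property: xa (poor/average boundary), xc (average/good), xp
#' (good/optimal). pH is the one decreasing-direction property (lower
#' alkalinity is better; thresholds descend 9, 8, 7).
#'
#' @return named list with elements xa, xc, xp, direction per property.
#' @export
default_fi_params <- function() {
  mk <- function(xa, xc, xp, direction = "increasing")
    list(xa = xa, xc = xc, xp = xp, direction = direction)
  list(TN = mk(0.75, 1.5, 2), TP = mk(0.4, 0.6, 1), TK = mk(5, 20, 25),
       AN = mk(60, 120, 180), AP = mk(5, 10, 20), AK = mk(50, 100, 200),
       OM = mk(10, 20, 30), pH = mk(9, 8, 7, direction = "decreasing"))
}

#' Piecewise non-dimensional fertility score Fi
#'
#' Increasing direction: Fi = ci/xa for ci <= xa; 1 + (ci-xa)/(xc-xa) on
#' (xa, xc]; 2 + (ci-xc)/(xp-xc) on (xc, xp]; 3 above xp. Decreasing
#' direction (pH): the branches mirrored on the reflected axis so the best
#' (lowest) values score 3: Fi = 3 for ci <= xp; 2 + (xc-ci)/(xc-xp) on
#' (xp, xc]; 1 + (xa-ci)/(xa-xc) on (xc, xa]; xa/ci above xa. Both forms are
#' continuous at every threshold and bounded by (0, 3].
#'
#' @param ci measured value(s), > 0.
#' @param params list with xa, xc, xp, direction (see
#'   [default_fi_params()]).
#' @return Fi score(s) in (0, 3].
#' @export
fi_score <- function(ci, params) {
  xa <- params$xa; xc <- params$xc; xp <- params$xp
  dir <- if (is.null(params$direction)) "increasing" else params$direction
  if (any(ci <= 0, na.rm = TRUE)) stop("ci must be > 0")
  if (dir == "increasing") {
    if (!(xa < xc && xc < xp))
      stop("increasing direction needs xa < xc < xp")
    ifelse(ci <= xa, ci / xa,
      ifelse(ci <= xc, 1 + (ci - xa) / (xc - xa),
        ifelse(ci <= xp, 2 + (ci - xc) / (xp - xc), 3)))
  } else {
    if (!(xa > xc && xc > xp))
      stop("decreasing direction needs xa > xc > xp")
    ifelse(ci <= xp, 3,
      ifelse(ci <= xc, 2 + (xc - ci) / (xc - xp),
        ifelse(ci <= xa, 1 + (xa - ci) / (xa - xc), xa / ci)))
  }
}

#' Improved Nemerow comprehensive fertility index
#'
#' F = sqrt((mean(Fi)^2 + min(Fi)^2) / 2) x (n-1)/n. The minimum replaces
#' the classical maximum (law-of-the-minimum reading: the scarcest nutrient
#' limits fertility) and the (n-1)/n amendment damps the index. A
#' consequence of the amendment is that the maximum attainable F at n = 8 is
#' 3 x 7/8 = 2.625, so the very-fertile class (F >= 2.70) is unreachable; a
#' warning flags this once per call when n = 8.
#'
#' @param fi vector of Fi scores in (0, 3], length n >= 2.
#' @param warn_unreachable warn that class I is unreachable at the default
#'   thresholds (default TRUE).
#' @return object of class `nemerow_result`: fbar, fmin, n, F, class.
#' @export
nemerow_F <- function(fi, warn_unreachable = TRUE) {
  if (!length(fi)) stop("empty Fi vector")
  if (length(fi) < 2) stop("need at least 2 Fi components")
  if (any(fi <= 0 | fi > 3)) stop("Fi components must lie in (0, 3]")
  n <- length(fi)
  fbar <- mean(fi); fmin <- min(fi)
  f <- sqrt((fbar^2 + fmin^2) / 2) * (n - 1) / n
  if (warn_unreachable && 3 * (n - 1) / n < 2.70)
    warning("maximum attainable F is ", format(3 * (n - 1) / n),
            " at n = ", n, "; the F >= 2.70 class cannot occur")
  structure(list(fi = fi, fbar = fbar, fmin = fmin, n = n, F = f,
                 class = classify_F(f)),
            class = "nemerow_result")
}

#' @export
print.nemerow_result <- function(x, ...) {
  cat(sprintf("nemerow_result: F = %.4f (class %s), Fbar = %.3f, Fmin = %.3f, n = %d\n",
              x$F, x$class, x$fbar, x$fmin, x$n))
  invisible(x)
}

#' Fertility class of a comprehensive index value
#'
#' F >= 2.70: I (very fertile); 1.80 <= F < 2.70: II (fertile);
#' 0.90 <= F < 1.80: III (general); F < 0.90: IV (barren).
#'
#' @param F comprehensive index value(s) >= 0.
#' @return character class(es) "I", "II", "III" or "IV".
#' @export
classify_F <- function(F) {
  ifelse(F >= 2.70, "I",
    ifelse(F >= 1.80, "II",
      ifelse(F >= 0.90, "III", "IV")))
}

#' Area fractions of a classified grid
#'
#' @param class_grid a `raster_grid` or matrix/vector of class labels
#'   (NA = nodata).
#' @return named numeric vector of fractions over valid cells, summing to 1.
#' @export
area_fractions <- function(class_grid) {
  v <- if (inherits(class_grid, "raster_grid")) class_grid$values
       else class_grid
  v <- v[!is.na(v)]
  if (!length(v)) stop("all cells are nodata")
  tab <- table(v)
  stats::setNames(as.numeric(tab) / length(v), names(tab))
}

#' Comprehensive fertility surface from eight property surfaces
#'
#' Applies [fi_score()] cellwise to each property surface, combines the
#' eight Fi grids through the improved Nemerow index, classifies the F grid
#' and reports per-class area fractions. Any nodata cell in any input
#' propagates to nodata in F.
#'
#' Kriged concentration surfaces can undershoot zero where the data are
#' sparse; such cells are physically impossible and are handled by the
#' `nonpositive` policy: "floor" (default) replaces them with the smallest
#' positive cell value of that surface, "na" blanks them, "error" aborts.
#'
#' @param surfaces named list of eight aligned `raster_grid`s (names =
#'   property names), on the measurement scale.
#' @param params Nemerow thresholds per property
#'   (default [default_fi_params()]).
#' @param nonpositive policy for cells <= 0 in a property surface.
#' @return object of class `fertility_result`: fi (list of grids), F grid,
#'   class grid, area fractions.
#' @export
fertility_surface <- function(surfaces, params = default_fi_params(),
                              nonpositive = c("floor", "na", "error")) {
  nonpositive <- match.arg(nonpositive)
  props <- names(surfaces)
  if (length(props) < 2) stop("need at least 2 property surfaces")
  miss <- setdiff(props, names(params))
  if (length(miss)) stop("no Nemerow thresholds for: ",
                         paste(miss, collapse = ", "))
  check_aligned(surfaces)
  tmpl <- surfaces[[1]]
  n <- length(props)
  fi <- lapply(props, function(p) {
    v <- surfaces[[p]]$values
    bad <- which(v <= 0)
    if (length(bad)) {
      if (nonpositive == "error")
        stop(p, ": ", length(bad), " non-positive cells")
      if (nonpositive == "na") v[bad] <- NA_real_
      else {
        pos <- v[v > 0]
        if (!length(pos)) stop(p, ": no positive cells")
        warning(p, ": ", length(bad),
                " non-positive cells floored to the smallest positive value")
        v[bad] <- min(pos)
      }
    }
    ok <- !is.na(v)
    out <- rep(NA_real_, length(v))
    out[ok] <- fi_score(v[ok], params[[p]])
    matrix(out, nrow(v))
  })
  names(fi) <- props
  stackm <- simplify2array(fi)              # rows x cols x n
  fbar <- apply(stackm, c(1, 2), mean)
  fmin <- apply(stackm, c(1, 2), min)
  Fv <- sqrt((fbar^2 + fmin^2) / 2) * (n - 1) / n
  cls <- classify_F(Fv)
  cls[is.na(Fv)] <- NA
  mk <- function(v) raster_grid(v, tmpl$xll, tmpl$yll, tmpl$cellsize)
  structure(list(
    fi = lapply(fi, mk),
    F = mk(Fv),
    class = structure(list(values = cls, xll = tmpl$xll, yll = tmpl$yll,
                           cellsize = tmpl$cellsize, nodata = tmpl$nodata),
                      class = "raster_grid"),
    fractions = area_fractions(cls),
    n = n),
    class = "fertility_result")
}

#' @export
print.fertility_result <- function(x, ...) {
  cat(sprintf("fertility_result: %d properties, class fractions:\n", x$n))
  print(round(x$fractions, 4))
  invisible(x)
}
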