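#' Raster grid container
#'
#' A minimal planar raster: a numeric matrix whose first row is the
#' northernmost row, georeferenced by the lower-left corner of the grid and a
#' square cell size. Coordinates are map units (metres); x increases east,
#' y increases north; cells are registered to their centres.
#'
#' @param values numeric matrix (row 1 = top/north row).
#' @param xll,yll x/y of the lower-left corner of the lower-left cell.
#' @param cellsize cell edge length in map units; must be > 0.
#' @param nodata value marking missing cells in files; stored cells use NA.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cellsize <= 0) stop("cellsize must be > 0")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll))
  ok <- is.finite(v)
  if (any(ok))
    cat(sprintf("  range [%g, %g], %d NA cells\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-centre coordinates of every cell
#'
#' @param grid a `raster_grid`.
#' @return data.frame with columns x, y, row, col in matrix order
#'   (column-major over the values matrix).
#' @export
grid_coords <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(
    x = grid$xll + (cols - 0.5) * grid$cellsize,
    y = grid$yll + (nr - rows + 0.5) * grid$cellsize,
    row = rows, col = cols)
}

#' Locate the cell containing each point
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates (map units).
#' @return data.frame with row, col; out-of-bounds points raise an error
#'   listing the offending indices.
#' @export
cell_index <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$xll) / grid$cellsize) + 1L
  row <- nr - floor((y - grid$yll) / grid$cellsize)
  bad <- which(col < 1L | col > nc | row < 1L | row > nr)
  if (length(bad))
    stop("points out of grid bounds: ", paste(bad, collapse = ", "))
  data.frame(row = row, col = col)
}

#' Sample a raster at point locations
#'
#' @param grid a `raster_grid`.
#' @param x,y point coordinates.
#' @param method "nearest" (value of the containing cell, the default) or
#'   "bilinear" (interpolation between the four surrounding cell centres).
#' @return numeric vector of sampled values.
#' @export
grid_extract <- function(grid, x, y, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  v <- grid$values
  if (method == "nearest") {
    idx <- cell_index(grid, x, y)
    return(v[cbind(idx$row, idx$col)])
  }
  nr <- nrow(v); nc <- ncol(v); cs <- grid$cellsize
  # fractional position in cell-centre coordinates
  fc <- (x - grid$xll) / cs + 0.5
  fr <- nr - (y - grid$yll) / cs + 0.5
  c0 <- pmin(pmax(floor(fc), 1L), nc - 1L); r0 <- pmin(pmax(floor(fr), 1L), nr - 1L)
  tc <- pmin(pmax(fc - c0, 0), 1); tr <- pmin(pmax(fr - r0, 0), 1)
  v00 <- v[cbind(r0, c0)]; v01 <- v[cbind(r0, c0 + 1L)]
  v10 <- v[cbind(r0 + 1L, c0)]; v11 <- v[cbind(r0 + 1L, c0 + 1L)]
  (1 - tr) * ((1 - tc) * v00 + tc * v01) + tr * ((1 - tc) * v10 + tc * v11)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[!is.finite(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)), con)
  writeLines(apply(v, 1L, function(r) paste(format(r, digits = 17), collapse = " ")),
             con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return a `raster_grid`; nodata cells become NA.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[a-zA-Z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed header at line ", i, ": ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(req, names(hdr))
  if (length(miss)) stop("header missing: ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows)
    stop("expected ", hdr$nrows, " data rows, found ", length(body))
  v <- matrix(NA_real_, hdr$nrows, hdr$ncols)
  for (r in seq_len(hdr$nrows)) {
    row <- as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]])
    if (length(row) != hdr$ncols)
      stop("row ", r, " (line ", i + r - 1L, "): expected ", hdr$ncols,
           " values, found ", length(row))
    v[r, ] <- row
  }
  v[v == nodata] <- NA_real_
  raster_grid(v, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

# shared shape/alignment check used by stack and fertility code
check_aligned <- function(grids) {
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        g$xll != ref$xll || g$yll != ref$yll || g$cellsize != ref$cellsize)
      stop("raster grids are not aligned (shape/origin/cellsize differ)")
  }
  invisible(TRUE)
}
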