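#' Spatial density grid
#'
#' A normalized raster carrier for utilization distributions: square cells of
#' edge `cell` (m), lower-left corner of the raster at `origin`, and a matrix
#' of density values (m^-2) with rows indexing x and columns indexing y.
#' Total mass `sum(values) * cell^2` must be 1 within 1%.
#'
#' @param origin length-2 lower-left corner of the raster (m).
#' @param cell cell edge length (m).
#' @param values nx x ny matrix of non-negative densities (m^-2).
#' @return an object of class `density_grid`.
#' @export
density_grid <- function(origin, cell, values) {
  stopifnot(length(origin) == 2L, cell > 0, is.matrix(values))
  if (any(values < 0)) stop("density values must be >= 0")
  g <- structure(list(origin = as.numeric(origin), cell = cell,
                      values = values), class = "density_grid")
  m <- grid_mass(g)
  if (m < 0.99 || m > 1.01)
    stop("density grid mass ", format(m), " outside [0.99, 1.01]")
  g
}

grid_mass <- function(g) sum(g$values) * g$cell^2

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid>", nrow(x$values), "x", ncol(x$values), "cells of",
      format(x$cell, digits = 5), "m; mass", format(grid_mass(x), digits = 5),
      "\n")
  invisible(x)
}

# cell-center coordinates along each axis
grid_axis <- function(g, axis) {
  n <- dim(g$values)[axis]
  g$origin[axis] + (seq_len(n) - 0.5) * g$cell
}

# geometry of the default raster: cells of sd/50 covering center +/- 5 sd
# (< 1% discretization error on coverage areas at this resolution)
make_grid_geometry <- function(center, sd_ref, cell = sd_ref / 50,
                               half_extent = 5 * sd_ref) {
  n <- ceiling(2 * half_extent / cell)
  origin <- center - n * cell / 2
  list(origin = origin, cell = cell, nx = n, ny = n)
}

# Accumulate a mixture of axis-aligned Gaussian components onto a raster by
# exact cell-mass integration (pnorm differences), each component evaluated
# only on the cells within 6 standard deviations of its mean.  sd = 0
# components drop their whole mass into the containing cell.  Returns the
# normalized density_grid.
rasterize_gaussian_mixture <- function(means, sds, geom, weights = NULL) {
  n <- nrow(means)
  if (is.null(weights)) weights <- rep(1 / n, n)
  vals <- matrix(0, geom$nx, geom$ny)
  xe <- geom$origin[1] + (0:geom$nx) * geom$cell   # cell edges
  ye <- geom$origin[2] + (0:geom$ny) * geom$cell
  for (i in seq_len(n)) {
    s <- sds[i]
    if (s <= 0) s <- 1e-12
    ix0 <- max(1L, findInterval(means[i, 1] - 6 * s, xe))
    ix1 <- min(geom$nx, findInterval(means[i, 1] + 6 * s, xe) + 1L)
    iy0 <- max(1L, findInterval(means[i, 2] - 6 * s, ye))
    iy1 <- min(geom$ny, findInterval(means[i, 2] + 6 * s, ye) + 1L)
    if (ix0 > geom$nx || ix1 < 1L || iy0 > geom$ny || iy1 < 1L) next
    px <- diff(pnorm(xe[ix0:(ix1 + 1L)], means[i, 1], s))
    py <- diff(pnorm(ye[iy0:(iy1 + 1L)], means[i, 2], s))
    vals[ix0:ix1, iy0:iy1] <- vals[ix0:ix1, iy0:iy1] +
      weights[i] * outer(px, py)
  }
  total <- sum(vals)
  if (total <= 0) stop("no probability mass fell on the raster")
  density_grid(geom$origin, geom$cell, vals / total / geom$cell^2)
}

# the q highest-density region as a cell mask: cells are ranked by density
# (ties broken by cell index, so the region is deterministic) and accumulated
# until the mass reaches q — the smallest cell set of the requested coverage
hdr_mask <- function(g, q) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- grid_mass(g)
  if (m < 0.99 || m > 1.01)
    stop("grid is not normalized (mass ", format(m), ")")
  v <- as.numeric(g$values)
  o <- order(v, decreasing = TRUE)
  cum <- cumsum(v[o]) * g$cell^2
  k <- which(cum >= q * m)[1]
  if (is.na(k)) k <- length(v)
  mask <- matrix(FALSE, nrow(g$values), ncol(g$values))
  sel <- o[seq_len(k)]
  mask[sel[v[sel] > 0]] <- TRUE
  mask
}

#' Highest-density-region area of a density grid
#'
#' Area of the smallest set of cells containing probability mass `q`: cells
#' are sorted by density (descending, ties broken by cell index) and
#' accumulated until the mass reaches `q`. Monotone non-decreasing in `q`.
#'
#' @param g a normalized [density_grid()].
#' @param q coverage quantile in (0, 1).
#' @return area in m^2.
#' @export
hdr_area <- function(g, q) {
  stopifnot(inherits(g, "density_grid"))
  sum(hdr_mask(g, q)) * g$cell^2
}

# map points onto linear cell indices; NA for points off the raster
point_cell_index <- function(g, points) {
  ix <- floor((points[, 1] - g$origin[1]) / g$cell) + 1L
  iy <- floor((points[, 2] - g$origin[2]) / g$cell) + 1L
  bad <- ix < 1L | ix > nrow(g$values) | iy < 1L | iy > ncol(g$values)
  idx <- (iy - 1L) * nrow(g$values) + ix
  idx[bad] <- NA_integer_
  idx
}

#' Write a density grid as an ESRI ASCII raster
#'
#' The plain-text `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by rows of density values (m^-2), top row = largest y.
#'
#' @param g a [density_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid_asc <- function(g, path) {
  stopifnot(inherits(g, "density_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", nrow(g$values)),
               paste("nrows", ncol(g$values)),
               paste("xllcorner", format(g$origin[1], digits = 12)),
               paste("yllcorner", format(g$origin[2], digits = 12)),
               paste("cellsize", format(g$cell, digits = 12)),
               "NODATA_value -9999"), con)
  for (j in rev(seq_len(ncol(g$values))))
    writeLines(paste(format(g$values[, j], digits = 8), collapse = " "), con)
  invisible(path)
}
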