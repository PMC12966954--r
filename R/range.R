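# GLS mean and ML stationary 2x2 covariance of a track under the fitted
# temporal correlation structure, computed through the whitening filter:
# Sigma[a, b] = sigma2_fit / n * sum_i E_ia E_ib / S_i with E the
# mean-profiled innovations (denominator n: ML, not REML).
gls_mean_cov <- function(model, x) {
  pm <- profile_mean(model, x)
  n <- nrow(pm$E)
  W <- pm$E / sqrt(pm$S)
  scale <- if (!is.null(model$sigma2)) model$sigma2 else model$diffusion
  Sigma <- crossprod(W) / n * scale
  list(mu = pm$mu, Sigma = (Sigma + t(Sigma)) / 2)
}

#' Gaussian range-distribution estimate
#'
#' The autocorrelated Gaussian density estimate of the range distribution: the
#' long-run marginal law of a range-resident movement process, summarized by
#' its `q` coverage ellipse. The center is the GLS mean under the fitted
#' correlation structure and the covariance is the ML stationary 2x2
#' covariance (per-axis variances and cross-covariance estimated under the
#' fitted temporal correlation). As a prediction of long-run space use it is
#' invariant, in expectation, to the sampling rate — in contrast with
#' [occurrence_density()].
#'
#' @param fitted a `fitted_model` of range-resident kind.
#' @param x the [track()].
#' @param q coverage quantile in (0, 1) (default 0.95).
#' @param isotropic force an isotropic covariance (average of the per-axis
#'   variances, zero cross-covariance).
#' @return a [gaussian_region()].
#' @export
gaussian_range <- function(fitted, x, q = 0.95, isotropic = FALSE) {
  stopifnot(inherits(fitted, "fitted_model"), inherits(x, "track"))
  m <- fitted$model
  if (!is_resident_kind(m$kind))
    stop("kind ", m$kind, " is not range-resident: no range distribution ",
         "exists (see range_residency_check)")
  gc <- gls_mean_cov(m, x)
  Sigma <- gc$Sigma
  if (isotropic) Sigma <- diag(rep(mean(diag(Sigma)), 2))
  gaussian_region(gc$mu, Sigma, q)
}

#' Confidence interval for an estimated coverage area
#'
#' Treats the estimated area as a scaled chi-square variate with
#' `nu = 2 * (n_eff - 1)` degrees of freedom, giving the interval
#' `area * nu / qchisq(c((1 + level)/2, (1 - level)/2), nu)`. The interval
#' always contains the point estimate and collapses onto it as the effective
#' sample size grows.
#'
#' @param region a [gaussian_region()].
#' @param n_eff effective sample size (range crossings), `> 1`.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(low, high)` in m^2.
#' @export
area_confidence_interval <- function(region, n_eff, level = 0.95) {
  stopifnot(inherits(region, "gaussian_region"))
  if (!is.finite(n_eff) || n_eff <= 1)
    stop("confidence interval undefined for n_eff <= 1")
  nu <- 2 * (n_eff - 1)
  c(low = region$area * nu / qchisq((1 + level) / 2, nu),
    high = region$area * nu / qchisq((1 - level) / 2, nu))
}

# full-bandwidth-matrix kernel density estimate on a raster, evaluated at
# cell centers (valid because the bandwidth is much wider than a cell) and
# renormalized to unit mass
kde_raster <- function(points, H, geom) {
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  if (any(ev$values <= 0)) stop("degenerate bandwidth/covariance matrix")
  Hinv <- ev$vectors %*% (t(ev$vectors) / ev$values)
  a <- Hinv[1, 1]; b <- Hinv[1, 2]; cc <- Hinv[2, 2]
  wmax <- 6 * sqrt(max(ev$values))
  xc <- geom$origin[1] + (seq_len(geom$nx) - 0.5) * geom$cell
  yc <- geom$origin[2] + (seq_len(geom$ny) - 0.5) * geom$cell
  vals <- matrix(0, geom$nx, geom$ny)
  for (i in seq_len(nrow(points))) {
    ix <- which(abs(xc - points[i, 1]) <= wmax)
    iy <- which(abs(yc - points[i, 2]) <= wmax)
    if (length(ix) == 0L || length(iy) == 0L) next
    dx <- xc[ix] - points[i, 1]
    dy <- yc[iy] - points[i, 2]
    w <- exp(-0.5 * outer(a * dx^2, cc * dy^2, `+`) - b * outer(dx, dy))
    vals[ix, iy] <- vals[ix, iy] + w
  }
  total <- sum(vals)
  if (total <= 0) stop("no probability mass fell on the raster")
  density_grid(geom$origin, geom$cell, vals / total / geom$cell^2)
}

#' Autocorrelated kernel density estimate of the range distribution
#'
#' Gaussian-kernel KDE over the observed locations whose bandwidth uses the
#' Gaussian reference rule with the *effective* sample size in place of the
#' nominal one: `H = Sigma_hat * n_eff^(-1/3)` (the d = 2 reference-rule
#' exponent). This corrects the bandwidth for autocorrelation; see
#' [conventional_kde()] for the nominal-n estimator it is contrasted with,
#' which undersmooths (and hence underestimates coverage areas) on
#' autocorrelated tracks.
#'
#' @param fitted a `fitted_model` of range-resident kind.
#' @param x the [track()].
#' @param geom optional raster geometry from `make_grid_geometry`; defaults
#'   to cells of `sd/50` covering the range center +/- 5 sd.
#' @return a [density_grid()].
#' @export
akde_density <- function(fitted, x, geom = NULL) {
  stopifnot(inherits(fitted, "fitted_model"))
  m <- fitted$model
  if (!is_resident_kind(m$kind))
    stop("kind ", m$kind, " is not range-resident (see range_residency_check)")
  gc <- gls_mean_cov(m, x)
  n_eff <- fitted$n_eff
  if (!is.finite(n_eff) || n_eff <= 1) stop("effective sample size too small")
  H <- gc$Sigma * n_eff^(-1 / 3)
  if (is.null(geom))
    geom <- make_grid_geometry(gc$mu, sqrt(mean(diag(gc$Sigma))))
  kde_raster(x$coords, H, geom)
}

#' Conventional kernel density estimate
#'
#' The IID-assuming KDE baseline: Gaussian reference-rule bandwidth
#' `H = S * n^(-1/3)` with `S` the ML sample covariance and `n` the nominal
#' number of locations.
#'
#' @param x a [track()].
#' @param geom optional raster geometry (see [akde_density()]).
#' @return a [density_grid()].
#' @export
conventional_kde <- function(x, geom = NULL) {
  stopifnot(inherits(x, "track"))
  n <- n_locations(x)
  mu <- colMeans(x$coords)
  S <- crossprod(sweep(x$coords, 2L, mu)) / n
  H <- S * n^(-1 / 3)
  if (is.null(geom)) geom <- make_grid_geometry(mu, sqrt(mean(diag(S))))
  kde_raster(x$coords, H, geom)
}

# shoelace polygon area
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Minimum convex polygon area
#'
#' Area of the convex hull of the track's locations. With `fraction < 1` the
#' points farthest from the centroid are peeled (ties broken by index) before
#' hulling, the classical percentage-MCP.
#'
#' @param x a [track()] or an n x 2 coordinate matrix, n >= 3.
#' @param fraction fraction of points retained, in (0, 1].
#' @return hull area in m^2; a degenerate (collinear) hull returns 0 with
#'   attribute `degenerate = TRUE`.
#' @export
mcp_area <- function(x, fraction = 1) {
  pts <- if (inherits(x, "track")) x$coords else as.matrix(x)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points for a convex hull")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction < 1) {
    ctr <- colMeans(pts)
    d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    keep <- order(d, seq_len(n))[seq_len(max(3L, ceiling(fraction * n)))]
    pts <- pts[sort(keep), , drop = FALSE]
  }
  h <- grDevices::chull(pts)
  area <- if (length(h) < 3L) 0 else polygon_area(pts[h, , drop = FALSE])
  if (area == 0) attr(area, "degenerate") <- TRUE
  area
}
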