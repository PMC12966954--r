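check_interpolatable <- function(model) {
  if (model$kind == "IID")
    stop("no informative interpolation: an IID fit carries no information ",
         "about unobserved locations — there must be detectable ",
         "autocorrelation in the movement process to estimate an ",
         "occurrence distribution")
}

# conditional Gaussian law of the position at the query times given all
# observations, by a fixed-interval two-pass smoother over the state
# recursion (query times enter the filter as unobserved epochs)
krige_path_impl <- function(model, x, times) {
  t1 <- x$times[1]; tn <- x$times[n_locations(x)]
  if (any(times < t1 - 1e-12) || any(times > tn + 1e-12))
    stop("extrapolation refused: query times must lie within [",
         format(t1), ", ", format(tn), "] days")
  center <- if (model$kind %in% c("BM", "IOU")) c(0, 0) else model$mu
  merged <- sort(unique(c(x$times, times)))
  Z <- matrix(NA_real_, length(merged), 2)
  oi <- match(x$times, merged)
  Z[oi, ] <- sweep(x$coords, 2L, center)
  kf <- kalman_run(model, merged, Z, smooth = TRUE)
  qi <- match(times, merged)
  data.frame(t = times,
             x = kf$xs[qi, 1] + center[1],
             y = kf$xs[qi, 2] + center[2],
             var = pmax(kf$vs[qi], 0))
}

#' Conditional location law at one time (time-series Kriging)
#'
#' The exact conditional Gaussian distribution of the animal's position at
#' time `t` given the whole observed track under the fitted autocorrelated
#' model (and its location-error variance). At an observation time with zero
#' location error the law collapses onto the observation; with positive error
#' it retains an error-variance floor. An `IID` fit is refused: without
#' detectable autocorrelation interpolation is uninformative.
#'
#' @param fitted a `fitted_model` of autocorrelated kind
#'   (`BM`/`OU`/`IOU`/`OUF`).
#' @param x the [track()].
#' @param t query time (days), within the observation window.
#' @return a `conditional_gaussian`: fields `t`, `mean` (length 2, m) and
#'   `cov` (2x2, m^2).
#' @export
krige_at <- function(fitted, x, t) {
  stopifnot(inherits(fitted, "fitted_model"), inherits(x, "track"),
            length(t) == 1L)
  check_interpolatable(fitted$model)
  kp <- krige_path_impl(fitted$model, x, t)
  structure(list(t = t, mean = c(kp$x, kp$y), cov = diag(rep(kp$var, 2))),
            class = "conditional_gaussian")
}

#' Kriged conditional path summary at many times
#'
#' Vectorized companion of [krige_at()]: the conditional means trace the most
#' likely path, the conditional variance quantifies interpolation uncertainty.
#'
#' @inheritParams krige_at
#' @param times query times (days) within the observation window.
#' @return data frame with columns `t`, `x`, `y` (conditional mean, m) and
#'   `var` (per-axis conditional variance, m^2).
#' @export
krige_path <- function(fitted, x, times) {
  stopifnot(inherits(fitted, "fitted_model"), inherits(x, "track"))
  check_interpolatable(fitted$model)
  krige_path_impl(fitted$model, x, times)
}

# observation gaps longer than gap_factor times the median interval; query
# times strictly inside one are skipped from the time average so that
# effectively unconditioned predictions do not oversmooth the estimate
skipped_gaps <- function(times, gap_factor) {
  dts <- diff(times)
  med <- median(dts)
  i <- which(dts > gap_factor * med)
  if (length(i) == 0L) return(NULL)
  cbind(start = times[i], end = times[i + 1])
}

#' Kriged occurrence distribution
#'
#' The time-averaged conditional location law given the observed track: the
#' conditional Gaussian at each query time (see [krige_at()]) is averaged
#' uniformly over an evenly spaced time grid spanning the observation window
#' and rasterized. Query times falling strictly inside skipped gaps
#' (observation intervals longer than `gap_factor` times the median sampling
#' interval) are excluded from the average. The result quantifies uncertainty
#' about the movement path within the window — not long-run space use — and
#' its coverage areas shrink as the sampling rate grows, collapsing onto the
#' path (zero area) in the infinite-rate limit.
#'
#' @param fitted a `fitted_model` of autocorrelated kind.
#' @param x the [track()], at least 2 locations.
#' @param geom optional raster geometry (see [akde_density()]); defaults to
#'   cells of `sd/50` covering the fitted range center +/- 5 sd (stationary
#'   fits) or the track's bounding region (diffusive fits).
#' @param gap_factor gap-skipping threshold, in multiples of the median
#'   sampling interval (default 3).
#' @param n_per_interval query-time density: number of query times per
#'   observation interval (default 10).
#' @param query_times optional explicit query times (days), overriding the
#'   even grid (used e.g. by holdout cross-validation to query exactly the
#'   held-out epochs).
#' @return a [density_grid()].
#' @export
occurrence_density <- function(fitted, x, geom = NULL, gap_factor = 3,
                               n_per_interval = 10, query_times = NULL) {
  stopifnot(inherits(fitted, "fitted_model"), inherits(x, "track"))
  check_interpolatable(fitted$model)
  n <- n_locations(x)
  if (n < 2L) stop("need at least 2 observations")
  if (is.null(query_times)) {
    nq <- n_per_interval * (n - 1L) + 1L
    query_times <- seq(x$times[1], x$times[n], length.out = nq)
  }
  gaps <- skipped_gaps(x$times, gap_factor)
  if (!is.null(gaps)) {
    keep <- rep(TRUE, length(query_times))
    for (g in seq_len(nrow(gaps)))
      keep <- keep & !(query_times > gaps[g, 1] & query_times < gaps[g, 2])
    query_times <- query_times[keep]
  }
  if (length(query_times) == 0L)
    stop("all query times fall inside skipped gaps")
  kp <- krige_path_impl(fitted$model, x, query_times)
  if (is.null(geom)) {
    m <- fitted$model
    if (!is.null(m$sigma2)) {
      geom <- make_grid_geometry(m$mu, sqrt(m$sigma2))
    } else {
      ctr <- colMeans(x$coords)
      spread <- sqrt(mean(sweep(x$coords, 2L, ctr)^2)) +
        3 * sqrt(max(kp$var))
      geom <- make_grid_geometry(ctr, spread)
    }
  }
  rasterize_gaussian_mixture(cbind(kp$x, kp$y), sqrt(kp$var), geom)
}

#' Brownian-bridge conditional variance
#'
#' Per-axis conditional variance of a Brownian motion at time `t` given its
#' positions at the bracketing times `t1 <= t <= t2`:
#' `D * (t - t1) * (t2 - t) / (t2 - t1)`. Zero at the endpoints, symmetric
#' about the midpoint, and reproduced exactly by [krige_at()] under a `BM`
#' fit when only the two bracketing observations are supplied — the Brownian
#' bridge movement model is time-series Kriging with a BM process.
#'
#' @param D diffusion rate (m^2/day).
#' @param t1,t2 bracketing observation times (days), `t1 < t2`.
#' @param t query time(s) in `[t1, t2]`.
#' @return conditional variance (m^2), vectorized over `t`.
#' @export
bbmm_variance <- function(D, t1, t2, t) {
  if (t1 >= t2) stop("t1 must precede t2")
  if (any(t < t1 | t > t2)) stop("t must lie within [t1, t2]")
  D * (t - t1) * (t2 - t) / (t2 - t1)
}

#' Expected value of a spatial covariate under a distribution grid
#'
#' Grid-weighted mean of a covariate raster aligned cell-for-cell with a
#' density grid — e.g. the expected vegetation cover along the uncertain
#' movement path when applied to an occurrence distribution.
#'
#' @param g a [density_grid()].
#' @param covariate matrix of covariate values, same dimensions as
#'   `g$values`.
#' @return the probability-weighted mean covariate value.
#' @export
covariate_expectation <- function(g, covariate) {
  stopifnot(inherits(g, "density_grid"),
            all(dim(covariate) == dim(g$values)))
  sum(covariate * g$values) / sum(g$values)
}
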