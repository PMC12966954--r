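#' Fraction of points covered by an estimated region
#'
#' For a [gaussian_region()], a point is covered when its squared Mahalanobis
#' distance from the center is at most the chi-square(2 df) `q`-quantile. For
#' a [density_grid()], a point is covered when it falls in a cell of the
#' `q` highest-density region (points off the raster count as uncovered).
#'
#' @param region a [gaussian_region()] or [density_grid()].
#' @param points n x 2 matrix of test locations (m).
#' @param q coverage quantile — required for a density grid, ignored for a
#'   Gaussian region (which carries its own).
#' @return fraction in `[0, 1]`.
#' @export
region_coverage <- function(region, points, q = NULL) {
  UseMethod("region_coverage")
}

#' @export
region_coverage.gaussian_region <- function(region, points, q = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("need at least one test point")
  d <- sweep(points, 2L, region$center)
  Si <- solve(region$cov)
  m2 <- rowSums((d %*% Si) * d)
  mean(m2 <= qchisq(region$q, df = 2))
}

#' @export
region_coverage.density_grid <- function(region, points, q = NULL) {
  if (is.null(q)) stop("q is required for density-grid coverage")
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("need at least one test point")
  mask <- hdr_mask(region, q)
  idx <- point_cell_index(region, points)
  inside <- !is.na(idx) & mask[ifelse(is.na(idx), 1L, idx)]
  mean(inside)
}

new_coverage_result <- function(label, q, fractions, n_test) {
  stopifnot(all(n_test >= 1))
  structure(list(estimator = label, q = q,
                 coverage = mean(fractions),
                 n_test = sum(n_test),
                 fractions = fractions,
                 n_test_each = n_test),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("<coverage_result> ", x$estimator, ": nominal ", 100 * x$q,
      "% -> empirical ", format(100 * x$coverage, digits = 4), "% (",
      length(x$fractions), " replicates, ", x$n_test, " test points)\n",
      sep = "")
  invisible(x)
}

#' Extrapolative half-sample cross-validation of range estimators
#'
#' The calibration test appropriate for a home-range estimator: for each
#' track, fit on the first (past) half, build the nominal-`q` Gaussian range
#' region, and score the fraction of second-half (future) locations it
#' contains. A calibrated estimator of the range distribution covers, on
#' average, a fraction `q` of future locations. Tracks whose first half fails
#' [range_residency_check()] are excluded from the mean and reported.
#'
#' @param tracks list of [track()]s.
#' @param q coverage quantile (default 0.95).
#' @param kind movement-model kind fitted to each first half.
#' @param error_var fixed location-error variance (m^2).
#' @param check_residency run [range_residency_check()] on each first half
#'   and drop failures (default TRUE).
#' @return a `coverage_result`; excluded track indices, if any, are attached
#'   as attribute `"excluded"`.
#' @export
crossval_range <- function(tracks, q = 0.95, kind = "OUF", error_var = 0,
                           check_residency = TRUE) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  fractions <- numeric(0); n_test <- integer(0); excluded <- integer(0)
  for (i in seq_along(tracks)) {
    halves <- split_half(tracks[[i]])
    fit <- fit_ml(halves$train, kind, error_var = error_var)
    if (check_residency && !isTRUE(range_residency_check(halves$train, fit))) {
      excluded <- c(excluded, i)
      next
    }
    region <- gaussian_range(fit, halves$train, q)
    fractions <- c(fractions, region_coverage(region, halves$test$coords))
    n_test <- c(n_test, n_locations(halves$test))
  }
  if (length(fractions) == 0L) stop("no track passed the residency check")
  res <- new_coverage_result(paste0("gaussian_range[", kind, "]"), q,
                             fractions, n_test)
  if (length(excluded)) attr(res, "excluded") <- excluded
  res
}

#' Within-period holdout cross-validation of occurrence estimators
#'
#' The calibration test appropriate for an occurrence estimator: withhold
#' every second location, fit the movement model to the retained locations,
#' build the occurrence distribution with query times at exactly the held-out
#' epochs, and score the fraction of held-out locations inside the nominal-`q`
#' highest-density region. The test set lies *within* the observation period
#' — scoring an occurrence estimate against future locations instead (the
#' range protocol of [crossval_range()]) systematically under-covers.
#'
#' @param x a [track()] with at least 8 locations, or a list of tracks.
#' @param q coverage quantile (default 0.95).
#' @param kind movement-model kind fitted to the retained locations.
#' @param error_var fixed location-error variance (m^2).
#' @param gap_factor gap-skipping threshold passed to [occurrence_density()];
#'   held-out epochs inside skipped gaps are not scored.
#' @param geom optional raster geometry override.
#' @return a `coverage_result`.
#' @export
crossval_occurrence <- function(x, q = 0.95, kind = "OUF", error_var = 0,
                                gap_factor = 3, geom = NULL) {
  tracks <- if (inherits(x, "track")) list(x) else x
  fractions <- numeric(0); n_test <- integer(0)
  for (tr in tracks) {
    n <- n_locations(tr)
    if (n < 8L) stop("need at least 8 locations for holdout cross-validation")
    keep <- seq(1L, n, by = 2L)
    hold <- setdiff(seq_len(n), keep)
    if (length(hold) < 1L) stop("holdout left no test points")
    if (length(keep) < 4L) stop("holdout leaves fewer than 4 training points")
    train <- track(tr$times[keep], tr$coords[keep, , drop = FALSE], id = tr$id)
    fit <- fit_ml(train, kind, error_var = error_var)
    ht <- tr$times[hold]
    inside <- ht >= train$times[1] & ht <= train$times[length(keep)]
    gaps <- skipped_gaps(train$times, gap_factor)
    if (!is.null(gaps)) {
      for (g in seq_len(nrow(gaps)))
        inside <- inside & !(ht > gaps[g, 1] & ht < gaps[g, 2])
    }
    ht <- ht[inside]; hp <- tr$coords[hold, , drop = FALSE][inside, , drop = FALSE]
    if (length(ht) < 1L) stop("all held-out epochs excluded")
    dens <- occurrence_density(fit, train, geom = geom,
                               gap_factor = gap_factor, query_times = ht)
    fractions <- c(fractions, region_coverage(dens, hp, q = q))
    n_test <- c(n_test, length(ht))
  }
  new_coverage_result(paste0("occurrence[", kind, "]"), q, fractions, n_test)
}
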