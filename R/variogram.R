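#' Empirical semivariogram of a track
#'
#' For all location pairs `i < j`, half the mean squared per-axis displacement
#' is accumulated into log-spaced lag bins. For a range-resident process the
#' variogram asymptotes at the stationary variance; endless diffusion shows as
#' unbounded growth.
#'
#' @param x a [track()] with at least 10 locations.
#' @param n_bins requested number of log-spaced lag bins; reduced (with a
#'   warning) when there are fewer pairs than bins.
#' @return data frame with columns `lag` (mean lag in the bin, days),
#'   `semivariance` (m^2) and `pairs`.
#' @export
empirical_variogram <- function(x, n_bins = 15) {
  stopifnot(inherits(x, "track"))
  n <- n_locations(x)
  if (n < 10L) stop("need at least 10 locations for a variogram")
  n_pairs <- n * (n - 1) / 2
  if (n_pairs < n_bins) {
    warning("fewer pairs than bins; reducing to ", n_pairs, " bins")
    n_bins <- n_pairs
  }
  dt_min <- min(diff(x$times))
  lag_max <- diff(range(x$times))
  edges <- exp(seq(log(dt_min), log(lag_max), length.out = n_bins + 1))
  edges[n_bins + 1] <- lag_max * (1 + 1e-12)

  sum_sv <- numeric(n_bins); sum_lag <- numeric(n_bins); cnt <- numeric(n_bins)
  for (i in seq_len(n - 1L)) {
    lags <- x$times[(i + 1):n] - x$times[i]
    dx <- x$coords[(i + 1):n, 1] - x$coords[i, 1]
    dy <- x$coords[(i + 1):n, 2] - x$coords[i, 2]
    sv <- 0.25 * (dx^2 + dy^2)   # 0.5 * per-axis mean of squared displacement
    b <- findInterval(lags, edges, rightmost.closed = TRUE)
    b[b < 1L] <- 1L; b[b > n_bins] <- n_bins
    sum_sv <- sum_sv + unname(tapply2(sv, b, n_bins))
    sum_lag <- sum_lag + unname(tapply2(lags, b, n_bins))
    cnt <- cnt + unname(tapply2(rep(1, length(b)), b, n_bins))
  }
  keep <- cnt > 0
  data.frame(lag = sum_lag[keep] / cnt[keep],
             semivariance = sum_sv[keep] / cnt[keep],
             pairs = cnt[keep])
}

# fast grouped sum into a fixed number of bins
tapply2 <- function(v, b, nb) {
  out <- numeric(nb)
  s <- rowsum(v, b)
  out[as.integer(rownames(s))] <- s
  out
}

#' Range-residency diagnostic
#'
#' A track supports range-distribution estimation only if the animal crossed
#' its home range repeatedly during the observation window. The check passes
#' when (a) the fitted kind is range-resident, (b) the effective sample size
#' is at least `min_n_eff` range crossings, and (c) the last third of the
#' empirical variogram bins lies within a relative tolerance band of the
#' fitted asymptote `sigma2 + error_var`.
#'
#' @param x a [track()].
#' @param fitted a `fitted_model` for `x`.
#' @param min_n_eff minimum effective sample size (default 5 range crossings).
#' @param tol relative half-width of the asymptote band (default 0.5).
#' @return logical verdict with a `diagnostics` attribute carrying the three
#'   component verdicts and the measured quantities.
#' @export
range_residency_check <- function(x, fitted, min_n_eff = 5, tol = 0.5) {
  stopifnot(inherits(fitted, "fitted_model"))
  m <- fitted$model
  resident_kind <- is_resident_kind(m$kind)
  enough_crossings <- !is.na(fitted$n_eff) && fitted$n_eff >= min_n_eff

  asymptote_ok <- FALSE
  rel_dev <- NA_real_
  if (resident_kind) {
    vg <- empirical_variogram(x)
    last_third <- tail(vg, ceiling(nrow(vg) / 3))
    asym <- m$sigma2 + m$error_var
    level <- sum(last_third$semivariance * last_third$pairs) /
      sum(last_third$pairs)
    rel_dev <- level / asym - 1
    asymptote_ok <- abs(rel_dev) <= tol
  }
  verdict <- resident_kind && enough_crossings && asymptote_ok
  attr(verdict, "diagnostics") <- list(
    resident_kind = resident_kind,
    enough_crossings = enough_crossings,
    asymptote_ok = asymptote_ok,
    n_eff = fitted$n_eff,
    relative_asymptote_deviation = rel_dev)
  verdict
}
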