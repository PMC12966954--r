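#' Configuration for the simulation experiments
#'
#' Bundles the generating OUF model and the sampling-design grid for the
#' sampling-rate, sampling-duration, ratio and cross-validation experiments.
#' The defaults reproduce the full study design — an OUF process with a daily
#' positional timescale sampled at 1 to 128 fixes/day for 4 to 4096 days,
#' 400 replicates — which is cluster-scale; pass reduced grids (e.g.
#' `replicates = 25`, `rates = c(1, 4, 16, 64)`,
#' `durations = c(16, 64, 256)`) for desk-scale runs. Replicate `r` always
#' uses seed `base_seed + r`, so any experiment re-run with the same
#' configuration reproduces its result table exactly.
#'
#' @param tau_p positional autocorrelation timescale (days).
#' @param tau_v velocity autocorrelation timescale (days).
#' @param sigma2 stationary per-axis variance (m^2).
#' @param error_var location-error variance (m^2).
#' @param rates sampling rates swept (fixes/day).
#' @param durations sampling durations swept (days).
#' @param replicates replicates per condition.
#' @param base_seed base RNG seed; replicate `r` uses `base_seed + r`.
#' @param q coverage quantile for areas.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(tau_p = 1, tau_v = 0.1, sigma2 = 1e6,
                              error_var = 0, rates = 2^(0:7),
                              durations = 2^(2:12), replicates = 400,
                              base_seed = 1, q = 0.95) {
  stopifnot(replicates >= 1, length(rates) >= 1, length(durations) >= 1,
            all(rates > 0), all(durations > 0))
  model <- movement_model("OUF", sigma2 = sigma2, tau_p = tau_p,
                          tau_v = tau_v, error_var = error_var)
  structure(list(model = model, rates = rates, durations = durations,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), q = q),
            class = "experiment_config")
}

# analytic truth: the generating model's own q coverage area
true_coverage_area <- function(config) {
  gaussian_coverage_area(diag(rep(config$model$sigma2, 2)), config$q)
}

# one replicate of the core estimation pipeline: simulate, fit OUF, measure
# the 95% range-region area and occurrence-HDR area.  Fit failures are
# logged and reported as NA, never allowed to abort a sweep.
sweep_replicate <- function(config, rate, duration, seed,
                            occurrence = TRUE) {
  out <- c(range = NA_real_, occurrence = NA_real_, n = NA_real_)
  tryCatch({
    tr <- simulate_track(config$model, sampling_schedule(duration, rate),
                         seed = seed)
    fit <- fit_ml(tr, "OUF", error_var = config$model$error_var)
    out["n"] <- n_locations(tr)
    out["range"] <- gaussian_range(fit, tr, config$q)$area
    if (occurrence)
      out["occurrence"] <- hdr_area(occurrence_density(fit, tr), config$q)
  }, error = function(e) {
    message("replicate failed (rate=", rate, ", duration=", duration,
            ", seed=", seed, "): ", conditionMessage(e))
  })
  out
}

sweep_table <- function(config, grid, occurrence = TRUE) {
  truth <- true_coverage_area(config)
  rows <- vector("list", nrow(grid) * config$replicates)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(config$replicates)) {
      res <- sweep_replicate(config, grid$rate[g], grid$duration[g],
                             config$base_seed + r, occurrence = occurrence)
      ests <- c("range", "occurrence")
      if (!occurrence) ests <- "range"
      for (est in ests) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          replicate = r, rate = grid$rate[g], duration = grid$duration[g],
          n_eff = grid$duration[g] / config$model$tau_p,
          estimator = est, area = unname(res[est]), true_area = truth,
          ratio = unname(res[est]) / truth)
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Sampling-rate sweep
#'
#' Simulates OUF tracks at each sampling rate (fixed duration), fits the OUF
#' model, and records the estimated 95% coverage areas of the range and
#' occurrence distributions as ratios to the generating model's analytic
#' truth. The occurrence ratio collapses toward zero as the rate grows (the
#' divergent limit); the range ratio shows no systematic rate trend.
#'
#' @param config an [experiment_config()].
#' @param duration fixed sampling duration (days, default 256).
#' @return long data frame with one row per replicate x rate x estimator:
#'   `replicate`, `rate`, `duration`, `n_eff`, `estimator`, `area`,
#'   `true_area`, `ratio`.
#' @export
run_rate_sweep <- function(config, duration = 256) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- data.frame(rate = config$rates, duration = duration)
  sweep_table(config, grid)
}

#' Sampling-duration sweep
#'
#' As [run_rate_sweep()] but sweeping the sampling duration at fixed rate:
#' the occurrence ratio rises toward (but stays below) 1 as the effective
#' sample size `duration / tau_p` grows (the convergent limit), while the
#' range ratio is unbiased at scale.
#'
#' @param config an [experiment_config()].
#' @param rate fixed sampling rate (fixes/day, default 8).
#' @return long data frame as in [run_rate_sweep()].
#' @export
run_duration_sweep <- function(config, rate = 8) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- data.frame(rate = rate, duration = config$durations)
  sweep_table(config, grid)
}

#' Occurrence-to-range area-ratio scan
#'
#' For every rate x duration combination in the configuration, records the
#' per-replicate ratio of the 95% occurrence-HDR area to the 95% Gaussian
#' range area, against the effective sampling rate (fixes per range crossing)
#' and effective sample size (range crossings). The ratio is below 1 in the
#' overwhelming majority of replicates and decreases with sampling rate.
#'
#' @param config an [experiment_config()].
#' @return data frame with columns `replicate`, `rate`, `duration`, `n_eff`,
#'   `eff_rate` (fixes per range crossing), `occurrence_area`, `range_area`,
#'   `ratio`.
#' @export
run_ratio_scan <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- expand.grid(rate = config$rates, duration = config$durations)
  rows <- vector("list", nrow(grid) * config$replicates)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(config$replicates)) {
      res <- sweep_replicate(config, grid$rate[g], grid$duration[g],
                             config$base_seed + r)
      k <- k + 1L
      rows[[k]] <- data.frame(
        replicate = r, rate = grid$rate[g], duration = grid$duration[g],
        n_eff = grid$duration[g] / config$model$tau_p,
        eff_rate = grid$rate[g] * config$model$tau_p,
        occurrence_area = unname(res["occurrence"]),
        range_area = unname(res["range"]),
        ratio = unname(res["occurrence"]) / unname(res["range"]))
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Cross-validation study on simulated tracks
#'
#' Runs both calibration protocols on simulated OUF ensembles at the nominal
#' 50% and 95% levels: (a) extrapolative half-sample cross-validation of the
#' Gaussian range region (fit on the first half, score future locations), and
#' (b) within-period holdout cross-validation of the Kriged occurrence
#' distribution (withhold every second point, score held-out locations).
#' Optionally adds the misuse contrast — scoring the first-half occurrence
#' distribution against *future* locations — which under-covers its nominal
#' level.
#'
#' @param config an [experiment_config()]; `config$replicates` tracks are
#'   used for the range protocol.
#' @param rate,duration sampling design of the range-protocol ensemble
#'   (default 4 fixes/day for 512 days).
#' @param occ_rate,occ_duration sampling design of the occurrence-protocol
#'   ensemble (default 100 fixes/day for 64 days).
#' @param occ_replicates replicates for the occurrence protocol (default
#'   `ceiling(config$replicates / 2)`).
#' @param qs nominal coverage levels (default `c(0.5, 0.95)`).
#' @param contrast also score the first-half occurrence estimate against
#'   future locations (default FALSE; costly).
#' @return data frame with one row per protocol x level: `protocol`, `q`,
#'   `coverage`, `replicates`, `n_test`; per-replicate fractions attached as
#'   attribute `"detail"`.
#' @export
run_crossval_study <- function(config, rate = 4, duration = 512,
                               occ_rate = 100, occ_duration = 64,
                               occ_replicates = NULL, qs = c(0.5, 0.95),
                               contrast = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(occ_replicates))
    occ_replicates <- ceiling(config$replicates / 2)
  detail <- list()

  # extrapolative half-sample CV of the Gaussian range region (one fit per
  # track, scored at every level)
  range_fr <- matrix(NA_real_, config$replicates, length(qs))
  occ_future_fr <- rep(NA_real_, config$replicates)
  for (r in seq_len(config$replicates)) {
    tr <- simulate_track(config$model, sampling_schedule(duration, rate),
                         seed = config$base_seed + r)
    halves <- split_half(tr)
    fit <- fit_ml(halves$train, "OUF",
                  error_var = config$model$error_var)
    for (j in seq_along(qs)) {
      region <- gaussian_range(fit, halves$train, qs[j])
      range_fr[r, j] <- region_coverage(region, halves$test$coords)
    }
    if (contrast) {
      dens <- occurrence_density(fit, halves$train)
      occ_future_fr[r] <- region_coverage(dens, halves$test$coords,
                                          q = max(qs))
    }
  }

  # within-period holdout CV of the occurrence distribution (one fit and one
  # density per replicate, scored at every level)
  occ_fr <- matrix(NA_real_, occ_replicates, length(qs))
  for (r in seq_len(occ_replicates)) {
    tr <- simulate_track(config$model,
                         sampling_schedule(occ_duration, occ_rate),
                         seed = config$base_seed + r)
    n <- n_locations(tr)
    keep <- seq(1L, n, by = 2L)
    hold <- setdiff(seq_len(n), keep)
    train <- track(tr$times[keep], tr$coords[keep, , drop = FALSE])
    fit <- fit_ml(train, "OUF", error_var = config$model$error_var)
    ht <- tr$times[hold]
    inside <- ht >= train$times[1] & ht <= train$times[length(keep)]
    ht <- ht[inside]
    hp <- tr$coords[hold, , drop = FALSE][inside, , drop = FALSE]
    dens <- occurrence_density(fit, train, query_times = ht)
    for (j in seq_along(qs))
      occ_fr[r, j] <- region_coverage(dens, hp, q = qs[j])
  }

  rows <- list()
  for (j in seq_along(qs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      protocol = "range_future", q = qs[j],
      coverage = mean(range_fr[, j]), replicates = config$replicates,
      n_test = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      protocol = "occurrence_holdout", q = qs[j],
      coverage = mean(occ_fr[, j]), replicates = occ_replicates,
      n_test = NA_real_)
  }
  if (contrast)
    rows[[length(rows) + 1L]] <- data.frame(
      protocol = "occurrence_future", q = max(qs),
      coverage = mean(occ_future_fr), replicates = config$replicates,
      n_test = NA_real_)
  out <- do.call(rbind, rows)
  attr(out, "detail") <- list(range_future = range_fr,
                              occurrence_holdout = occ_fr,
                              occurrence_future = occ_future_fr, qs = qs)
  out
}

#' Read an experiment configuration from YAML
#'
#' A flat mapping of the [experiment_config()] arguments (`tau_p`, `tau_v`,
#' `sigma2`, `error_var`, `rates`, `durations`, `replicates`, `base_seed`,
#' `q`); absent keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(experiment_config))
  bad <- setdiff(names(y), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  # YAML 1.1 reads exponent literals without a sign ("4.0e6") as strings
  y <- lapply(y, function(v) if (is.character(v)) as.numeric(v) else v)
  do.call(experiment_config, y)
}
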