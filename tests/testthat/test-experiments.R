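small_config <- function(...) {
  experiment_config(rates = c(1, 8), durations = c(16, 32), replicates = 3,
                    base_seed = 123, ...)
}

test_that("experiment config validates and carries the generating model", {
  cfg <- experiment_config()
  expect_equal(cfg$rates, 2^(0:7))
  expect_equal(cfg$durations, 2^(2:12))
  expect_equal(cfg$replicates, 400L)
  expect_equal(cfg$model$tau_p, 1)
  expect_error(experiment_config(replicates = 0), "replicates")
  expect_error(experiment_config(rates = numeric(0)), "rates")
})

test_that("rate sweep bookkeeping: complete rows, exact ratios, determinism", {
  cfg <- small_config()
  res <- run_rate_sweep(cfg, duration = 16)
  expect_equal(nrow(res), 3 * 2 * 2)   # replicates x rates x estimators
  expect_setequal(unique(res$estimator), c("range", "occurrence"))
  expect_equal(res$ratio, res$area / res$true_area)
  expect_equal(unique(res$true_area),
               gaussian_coverage_area(diag(rep(1e6, 2)), 0.95))
  res2 <- run_rate_sweep(cfg, duration = 16)
  expect_identical(res, res2)   # full determinism from base_seed
})

test_that("duration sweep records the effective sample size by definition", {
  cfg <- small_config()
  res <- run_duration_sweep(cfg, rate = 8)
  expect_equal(sort(unique(res$n_eff)), c(16, 32) / cfg$model$tau_p)
  expect_equal(nrow(res), 3 * 2 * 2)
})

test_that("occurrence ratios fall with rate and rise with duration", {
  cfg <- experiment_config(rates = c(1, 8, 64), durations = c(16, 64),
                           replicates = 4, base_seed = 7)
  rs <- run_rate_sweep(cfg, duration = 32)
  occ <- with(rs[rs$estimator == "occurrence", ],
              tapply(ratio, rate, mean))
  expect_true(all(diff(occ[order(as.numeric(names(occ)))]) < 0))
  rng <- with(rs[rs$estimator == "range", ], tapply(ratio, rate, mean))
  expect_lt(max(abs(rng - 1)), 0.35)   # no collapse for the range estimator

  ds <- run_duration_sweep(cfg, rate = 8)
  occ_d <- with(ds[ds$estimator == "occurrence", ],
                tapply(ratio, duration, mean))
  occ_d <- occ_d[order(as.numeric(names(occ_d)))]
  expect_true(all(diff(occ_d) > 0))
  expect_true(all(occ_d < 1))
})

test_that("ratio scan reports occurrence:range below one, falling in rate", {
  cfg <- experiment_config(rates = c(2, 32), durations = 64,
                           replicates = 4, base_seed = 11)
  rs <- run_ratio_scan(cfg)
  expect_equal(nrow(rs), 2 * 4)
  expect_equal(rs$ratio, rs$occurrence_area / rs$range_area)
  expect_gt(mean(rs$ratio < 1), 0.9)
  m_lo <- mean(rs$ratio[rs$rate == 2]); m_hi <- mean(rs$ratio[rs$rate == 32])
  expect_lt(m_hi, m_lo)
})

test_that("crossval study emits both protocols at both levels", {
  cfg <- experiment_config(replicates = 3, base_seed = 21)
  out <- run_crossval_study(cfg, rate = 4, duration = 64,
                            occ_rate = 16, occ_duration = 16,
                            occ_replicates = 2)
  expect_setequal(unique(out$protocol),
                  c("range_future", "occurrence_holdout"))
  expect_setequal(unique(out$q), c(0.5, 0.95))
  expect_equal(nrow(out), 4)
  expect_true(all(out$coverage >= 0 & out$coverage <= 1))
  detail <- attr(out, "detail")
  expect_equal(dim(detail$range_future), c(3, 2))
})

test_that("planar track CSV round-trips exactly", {
  m <- ouf_default()
  tr <- simulate_track(m, sampling_schedule(8, 4), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_track(tr, path)
  tr2 <- read_track(path)
  expect_equal(tr2$times, tr$times, tolerance = 1e-9)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-9)
})

test_that("Movebank dialect projects about the mean location", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    timestamp = c("2020-01-01 00:00:00", "2020-01-01 01:00:00",
                  "2020-01-01 02:00:00"),
    lon = c(10, 10, 10), lat = c(60, 60, 60),
    id = "a1", check.names = FALSE)
  names(df) <- c("timestamp", "location-long", "location-lat",
                 "individual-local-identifier")
  # single point location: projects to the origin
  write.csv(df, path, row.names = FALSE)
  tr <- read_track(path)
  expect_equal(unname(tr$coords), matrix(0, 3, 2), tolerance = 1e-9)
  expect_equal(tr$times, c(0, 1, 2) / 24)
  # one degree of longitude at latitude 60: R cos(60) pi/180 meters
  df2 <- df
  df2[["location-long"]] <- c(9.5, 10, 10.5)
  write.csv(df2, path, row.names = FALSE)
  tr2 <- read_track(path)
  expect_equal(tr2$coords[3, 1] - tr2$coords[1, 1],
               6371008.8 * cos(60 * pi / 180) * pi / 180,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(tr2$coords[3, 1] - tr2$coords[1, 1], 55597.4,
               tolerance = 1e-4, ignore_attr = TRUE)
  # multi-individual files split by identifier
  df3 <- rbind(df, df)
  df3[["individual-local-identifier"]] <- rep(c("a1", "b2"), each = 3)
  write.csv(df3, path, row.names = FALSE)
  trs <- read_track(path)
  expect_named(trs, c("a1", "b2"))
  # unknown columns produce a dialect error
  write.csv(data.frame(a = 1, b = 2), path, row.names = FALSE)
  expect_error(read_track(path), "dialect")
})

test_that("experiment configs read from YAML and grids export as ASCII", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tau_p: 2.0", "sigma2: 4.0e6", "rates: [1, 4]",
               "replicates: 5", "base_seed: 9"), path)
  cfg <- read_experiment_config(path)
  expect_equal(cfg$model$tau_p, 2)
  expect_equal(cfg$model$sigma2, 4e6)
  expect_equal(cfg$rates, c(1, 4))
  expect_equal(cfg$replicates, 5L)
  writeLines("bogus_key: 1", path)
  expect_error(read_experiment_config(path), "unknown config keys")

  g <- density_grid(c(-10, 20), 2, matrix(1 / 400, 10, 10))
  asc <- withr::local_tempfile(fileext = ".asc")
  write_grid_asc(g, asc)
  lines <- readLines(asc)
  expect_match(lines[1], "^ncols 10$")
  expect_match(lines[3], "^xllcorner -10$")
  expect_match(lines[5], "^cellsize 2$")
  expect_length(lines, 6 + 10)
})
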