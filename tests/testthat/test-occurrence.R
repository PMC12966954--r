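fake_fit <- function(model, n_eff = 50) {
  structure(list(model = model, n_eff = n_eff, convergence = TRUE,
                 loglik = NA_real_, k = param_count_for_test(model$kind),
                 n = NA_integer_, aicc = NA_real_),
            class = "fitted_model")
}
param_count_for_test <- function(kind)
  switch(kind, IID = 3L, OU = 4L, OUF = 5L, BM = 1L, IOU = 2L)

test_that("kriging interpolates through exact observations", {
  m <- movement_model("OU", sigma2 = 1e6, tau_p = 1)
  tr <- simulate_track(m, seq(0, 10, 0.5), seed = 71)
  f <- fake_fit(m)
  cg <- krige_at(f, tr, 3.5)
  expect_s3_class(cg, "conditional_gaussian")
  expect_equal(cg$mean, unname(tr$coords[tr$times == 3.5, ]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(max(abs(cg$cov)), 0, tolerance = 1e-6)
  # with location error the conditional keeps an error-variance floor
  me <- movement_model("OU", sigma2 = 1e6, tau_p = 1, error_var = 100)
  cge <- krige_at(fake_fit(me), tr, 3.5)
  expect_gt(cge$cov[1, 1], 0)
  expect_lte(cge$cov[1, 1], 100 + 1e-6)
})

test_that("kriging under BM with two observations is the Brownian bridge", {
  D <- 1
  m <- movement_model("BM", diffusion = D)
  tr <- track(c(0, 1), rbind(c(0, 0), c(10, -10)))
  f <- fake_fit(m)
  for (t in c(0.1, 0.25, 0.5, 0.9)) {
    cg <- krige_at(f, tr, t)
    expect_equal(cg$cov[1, 1], bbmm_variance(D, 0, 1, t), tolerance = 1e-10)
    # the bridge mean is the linear interpolant
    expect_equal(cg$mean, c(10 * t, -10 * t), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(bbmm_variance(1, 0, 1, 0.5), 0.25)
  expect_equal(bbmm_variance(1, 0, 1, 0), 0)
  ts <- seq(0, 1, 0.05)
  expect_equal(bbmm_variance(2, 0, 1, ts), bbmm_variance(2, 0, 1, 1 - ts))
  expect_error(bbmm_variance(1, 0, 1, 2), "within")
})

test_that("smoother agrees with dense GP regression on stationary kinds", {
  set.seed(72)
  for (kind in c("OU", "OUF")) {
    for (rep in 1:4) {
      m <- random_model(kind, error_var = sample(c(0, 0.2), 1))
      tt <- sort(runif(40, 0, 20))
      tr <- simulate_track(m, tt, seed = 720 + rep)
      qt <- sort(runif(13, min(tt), max(tt)))
      kp <- krige_path(fake_fit(m), tr, qt)
      or <- dense_krige(m, tr, qt)
      expect_equal(kp$x, or$x, tolerance = 1e-8)
      expect_equal(kp$y, or$y, tolerance = 1e-8)
      expect_equal(kp$var, or$var, tolerance = 1e-8)
      # conditional variance never exceeds the stationary variance
      expect_true(all(kp$var <= m$sigma2 + 1e-9))
    }
  }
})

test_that("IID fits and out-of-window queries are refused", {
  m <- movement_model("IID", sigma2 = 1)
  tr <- simulate_track(m, 0:20, seed = 73)
  expect_error(krige_at(fake_fit(m), tr, 5), "detectable autocorrelation")
  mo <- movement_model("OU", sigma2 = 1, tau_p = 1)
  expect_error(krige_at(fake_fit(mo), tr, 21.5), "extrapolation")
  expect_error(occurrence_density(fake_fit(m), tr),
               "detectable autocorrelation")
})

grid_mass_for_test <- function(g) sum(g$values) * g$cell^2

test_that("occurrence density normalizes and is time-reversal symmetric", {
  m <- movement_model("OU", sigma2 = 1e4, tau_p = 1)
  tr <- simulate_track(m, seq(0, 8, 0.25), seed = 74)
  f <- fake_fit(m)
  d <- occurrence_density(f, tr)
  expect_lt(abs(grid_mass_for_test(d) - 1), 0.01)
  # reversing the track in time leaves the time-averaged density unchanged
  rev_tr <- track(max(tr$times) - rev(tr$times),
                  tr$coords[rev(seq_len(n_locations(tr))), ])
  d_rev <- occurrence_density(f, rev_tr)
  expect_equal(d$values, d_rev$values, tolerance = 1e-8)
})

test_that("occurrence areas collapse as the same path is sampled faster", {
  m <- ouf_default()
  fine <- simulate_track(m, sampling_schedule(32, 16), seed = 75)
  areas <- vapply(c(16L, 4L, 1L), function(k) {   # rates 1, 4, 16 / day
    tr <- thin_track(fine, k)
    f <- fit_ml(tr, "OUF")
    hdr_area(occurrence_density(f, tr), 0.95)
  }, 0)
  expect_true(all(diff(areas) < 0))  # strictly decreasing in rate
})

test_that("gap-skipping removes query times inside long gaps", {
  m <- movement_model("OU", sigma2 = 1e4, tau_p = 1)
  sch <- sampling_schedule(20, 4, gaps = list(c(8, 14)))
  tr <- simulate_track(m, sch, seed = 76)
  f <- fake_fit(m)
  d_skip <- occurrence_density(f, tr, gap_factor = 3)
  d_keep <- occurrence_density(f, tr, gap_factor = 1e9)
  # not skipping the gap oversmooths: a wider (larger-area) 95% HDR
  expect_gt(hdr_area(d_keep, 0.95), hdr_area(d_skip, 0.95))
})

test_that("HDR areas: uniform, delta and rasterized-Gaussian cases", {
  # uniform density over 100 cells: q = 0.5 keeps half the cells
  vals <- matrix(1 / (100 * 4), 10, 10)  # cell = 2 m -> mass 1
  g <- density_grid(c(0, 0), 2, vals)
  expect_equal(hdr_area(g, 0.5), 50 * 4)
  expect_equal(hdr_area(g, 0.95), 95 * 4)
  # single occupied cell holds every level set
  vals2 <- matrix(0, 10, 10); vals2[4, 7] <- 1 / 4
  g2 <- density_grid(c(0, 0), 2, vals2)
  for (q in c(0.05, 0.5, 0.95)) expect_equal(hdr_area(g2, q), 4)
  # rasterized Gaussian matches the closed-form ellipse within 2%
  geom <- rvo:::make_grid_geometry(c(0, 0), 1000)
  gg <- rvo:::rasterize_gaussian_mixture(matrix(0, 1, 2), 1000, geom)
  expect_lt(abs(hdr_area(gg, 0.95) /
                gaussian_coverage_area(diag(c(1e6, 1e6)), 0.95) - 1), 0.02)
  # monotone in q
  qs <- seq(0.1, 0.9, 0.2)
  expect_true(all(diff(vapply(qs, function(q) hdr_area(gg, q), 0)) > 0))
  # unnormalized grids are rejected
  g_bad <- g; g_bad$values <- g$values * 2
  expect_error(hdr_area(g_bad, 0.5), "not normalized")
})

test_that("covariate expectation is the density-weighted mean", {
  vals <- matrix(1 / 400, 10, 10)
  g <- density_grid(c(0, 0), 2, vals)
  cov <- matrix(7, 10, 10)
  expect_equal(covariate_expectation(g, cov), 7)
  cov2 <- matrix(0, 10, 10); cov2[1:5, ] <- 2
  expect_equal(covariate_expectation(g, cov2), 1)
})
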