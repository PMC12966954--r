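test_that("process taxonomy reproduces the capability table exactly", {
  flags <- do.call(rbind, lapply(c("IID", "BM", "OU", "IOU", "OUF"),
                                 process_flags))
  # position autocorrelation absent only for IID
  expect_equal(flags$position_autocorrelated,
               c(FALSE, TRUE, TRUE, TRUE, TRUE))
  # velocity autocorrelation present only for IOU and OUF
  expect_equal(flags$velocity_autocorrelated,
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # range residency present only for IID, OU and OUF
  expect_equal(flags$range_resident, c(TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("model constructor validates parameters and coerces limits", {
  expect_error(movement_model("OU", sigma2 = 1), "tau_p")
  expect_error(movement_model("OUF", sigma2 = 1, tau_p = 1, tau_v = 2),
               "tau_p > tau_v")
  expect_error(movement_model("BM"), "diffusion")
  expect_error(movement_model("IID", sigma2 = -1), "sigma2")
  # infinite tau_p coerces OU -> BM and OUF -> IOU, requiring a diffusion
  bm <- movement_model("OU", tau_p = Inf, diffusion = 2)
  expect_identical(bm$kind, "BM")
  iou <- movement_model("OUF", tau_p = Inf, diffusion = 2, tau_v = 0.5)
  expect_identical(iou$kind, "IOU")
  expect_error(movement_model("OU", tau_p = Inf, sigma2 = 1), "diffusion")
})

test_that("autocovariance matches the closed-form kernels", {
  ou <- movement_model("OU", sigma2 = 1, tau_p = 1)
  expect_equal(autocovariance(ou, 0), 1)
  expect_equal(autocovariance(ou, 1), exp(-1), tolerance = 1e-12)
  ouf <- movement_model("OUF", sigma2 = 1, tau_p = 2, tau_v = 1)
  expect_equal(autocovariance(ouf, 1), 2 * exp(-1 / 2) - exp(-1),
               tolerance = 1e-12)
  iid <- movement_model("IID", sigma2 = 3)
  expect_equal(autocovariance(iid, 0), 3)
  expect_equal(autocovariance(iid, 0.001), 0)
  # continuous, non-increasing, value sigma2 at 0
  lags <- seq(0, 20, by = 0.01)
  a <- autocovariance(ouf, lags)
  expect_true(all(diff(a) <= 1e-12))
  expect_equal(a[1], ouf$sigma2)
  # diffusive kinds are refused with a pointer to the semivariance
  bm <- movement_model("BM", diffusion = 1)
  expect_error(autocovariance(bm, 1), "no stationary autocovariance")
})

test_that("OUF kernel is continuous into its OU and degenerate limits", {
  ou <- movement_model("OU", sigma2 = 2, tau_p = 3)
  near <- movement_model("OUF", sigma2 = 2, tau_p = 3, tau_v = 3e-8)
  for (lag in c(0.1, 1, 10) * 3)
    expect_equal(autocovariance(near, lag), autocovariance(ou, lag),
                 tolerance = 1e-6)
  # tau_v -> tau_p approaches the analytic (1 + lag/tau) exp(-lag/tau) limit
  close <- movement_model("OUF", sigma2 = 1, tau_p = 1, tau_v = 1 - 1e-9)
  expect_equal(autocovariance(close, 0.7), (1 + 0.7) * exp(-0.7),
               tolerance = 1e-8)
})

test_that("semivariance forms, identity and asymptotics hold", {
  bm <- movement_model("BM", diffusion = 2)
  expect_equal(semivariance(bm, 3), 6)
  expect_equal(semivariance(bm, 0), 0)
  ou <- movement_model("OU", sigma2 = 1, tau_p = 1)
  expect_equal(semivariance(ou, 1e9), 1, tolerance = 1e-12)
  iou <- movement_model("IOU", diffusion = 2, tau_v = 0.5)
  expect_equal(semivariance(iou, 0), 0)
  # stationary identity semivariance = acv(0) - acv(lag), exact
  ouf <- movement_model("OUF", sigma2 = 4, tau_p = 2, tau_v = 0.3)
  lags <- c(0, 0.05, 0.7, 3, 40)
  expect_identical(semivariance(ouf, lags),
                   autocovariance(ouf, 0) - autocovariance(ouf, lags))
  # non-decreasing in lag for every kind
  for (m in list(bm, ou, iou, ouf))
    expect_true(all(diff(semivariance(m, seq(0, 50, 0.1))) >= -1e-10))
  expect_error(semivariance(ou, -1), "lag")
})

test_that("transition law is exact: closed forms and kernel consistency", {
  ou <- movement_model("OU", sigma2 = 1, tau_p = 1)
  tr <- transition(ou, 1)
  expect_equal(tr$Phi[1, 1], exp(-1), tolerance = 1e-12)
  expect_equal(tr$Q[1, 1], 1 - exp(-2), tolerance = 1e-12)
  # mixing to stationarity
  tr_inf <- transition(ou, 1e4)
  expect_equal(tr_inf$Phi[1, 1], 0, tolerance = 1e-12)
  expect_equal(tr_inf$Q[1, 1], ou$sigma2, tolerance = 1e-12)
  expect_error(transition(ou, 0), "dt")
  # BM: unit multiplier, linear noise
  bm <- movement_model("BM", diffusion = 3)
  expect_equal(transition(bm, 2)$Q[1, 1], 6)
  expect_equal(transition(bm, 2)$Phi[1, 1], 1)
  # joint covariance implied by the transition equals the kernel, across
  # 4 orders of magnitude in dt (Cov(x_t, x_{t+dt}) = [Phi S]_{11})
  ouf <- movement_model("OUF", sigma2 = 2.5, tau_p = 1.7, tau_v = 0.23)
  S <- diag(c(ouf$sigma2, ouf$sigma2 / (ouf$tau_p * ouf$tau_v)))
  for (dt in c(0.01, 0.1, 1, 10, 100)) {
    tq <- transition(ouf, dt)
    expect_equal((tq$Phi %*% S)[1, 1], autocovariance(ouf, dt),
                 tolerance = 1e-10)
    # stationarity: S = Phi S Phi' + Q
    expect_equal(tq$Phi %*% S %*% t(tq$Phi) + tq$Q, S, tolerance = 1e-10)
    # spectral radius at most 1 for a stationary kind
    expect_lte(max(Mod(eigen(tq$Phi)$values)), 1 + 1e-12)
  }
})

test_that("gaussian coverage area follows the chi-square ellipse law", {
  expect_equal(gaussian_coverage_area(diag(2), 0.95), pi * qchisq(0.95, 2),
               tolerance = 1e-12)
  expect_equal(gaussian_coverage_area(diag(2), 0.95), 18.8222,
               tolerance = 1e-4)
  # area increasing in q, vanishing as q -> 0
  qs <- c(1e-8, seq(0.05, 0.95, 0.05))
  areas <- gaussian_coverage_area(diag(2), qs)
  expect_true(all(diff(areas) > 0))
  expect_lt(areas[1], 1e-6)
  # doubling both axis standard deviations quadruples the area
  expect_equal(gaussian_coverage_area(4 * diag(2), 0.9),
               4 * gaussian_coverage_area(diag(2), 0.9))
  expect_error(gaussian_coverage_area(matrix(c(1, 2, 2, 1), 2), 0.5),
               "positive definite")
  expect_error(gaussian_coverage_area(diag(2), 1), "q")
})

test_that("gaussian_region carries the closed-form area, increasing in q", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  r1 <- gaussian_region(c(0, 0), S, 0.5)
  r2 <- gaussian_region(c(0, 0), S, 0.95)
  expect_equal(r1$area, gaussian_coverage_area(S, 0.5))
  expect_lt(r1$area, r2$area)
})

test_that("models serialize to YAML and back", {
  m <- movement_model("OUF", mu = c(10, -5), sigma2 = 1e6, tau_p = 1,
                      tau_v = 0.1, error_var = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2[names(m2) != "mu"], m[names(m) != "mu"],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(m2$mu, m$mu)
})
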