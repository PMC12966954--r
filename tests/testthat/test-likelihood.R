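test_that("filter likelihood equals the dense-kernel oracle for all kinds", {
  set.seed(42)
  for (kind in c("IID", "OU", "OUF", "BM", "IOU")) {
    for (rep in 1:6) {
      ev <- sample(c(0, 0.3), 1)
      m <- random_model(kind, error_var = ev)
      tt <- sort(runif(sample(10:60, 1), 0, 30))
      origin <- if (kind %in% c("BM", "IOU")) rnorm(2) else NULL
      tr <- simulate_track(m, tt, seed = 100 + rep, origin = origin)
      expect_equal(model_loglik(m, tr), dense_loglik(m, tr),
                   tolerance = 1e-8,
                   label = paste("filter ll", kind, "rep", rep))
    }
  }
})

test_that("single IID location at the mean gives the standard-normal density", {
  m <- movement_model("IID", mu = c(0, 0), sigma2 = 1)
  tr <- track(0, matrix(0, 1, 2))
  expect_equal(model_loglik(m, tr), 2 * (-0.5 * log(2 * pi)),
               tolerance = 1e-12)
})

test_that("BM likelihood factorizes over independent increments", {
  m <- movement_model("BM", diffusion = 7)
  tt <- sort(runif(20, 0, 10))
  tr <- simulate_track(m, tt, seed = 8, origin = c(0, 0))
  ll_inc <- sum(vapply(1:2, function(a) {
    dx <- diff(tr$coords[, a]); dt <- diff(tr$times)
    sum(dnorm(dx, 0, sqrt(7 * dt), log = TRUE))
  }, 0))
  expect_equal(model_loglik(m, tr), ll_inc, tolerance = 1e-10)
})

test_that("ML fitting recovers OU parameters within 3 standard errors", {
  m <- movement_model("OU", mu = c(50, -20), sigma2 = 1, tau_p = 1)
  tr <- simulate_track(m, 0:1023, seed = 21)
  f <- fit_ml(tr, "OU", se = TRUE)
  expect_true(f$convergence)
  expect_lt(abs(f$model$tau_p - 1), 3 * f$se[["tau_p"]])
  expect_lt(abs(f$model$sigma2 - 1), 3 * f$se[["sigma2"]])
  expect_equal(f$k, 4L)
  expect_equal(f$n_eff, 1023 / f$model$tau_p)
})

test_that("fitting is translation-equivariant", {
  m <- ouf_default()
  tr <- simulate_track(m, sampling_schedule(64, 4), seed = 31)
  f1 <- fit_ml(tr, "OUF")
  tr2 <- track(tr$times, tr$coords + 5000)
  f2 <- fit_ml(tr2, "OUF")
  expect_equal(f2$model$mu, f1$model$mu + 5000, tolerance = 1e-4)
  expect_equal(f2$model$sigma2, f1$model$sigma2, tolerance = 1e-6)
  expect_equal(f2$model$tau_p, f1$model$tau_p, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("AICc prefers IID on independent data and OUF on OUF data", {
  wins_iid <- vapply(1:40, function(r) {
    tr <- simulate_track(movement_model("IID", sigma2 = 1), 0:511,
                         seed = 7000 + r)
    s <- select_model(tr, c("IID", "OU"))
    s$model$kind == "IID"
  }, TRUE)
  expect_gt(mean(wins_iid), 0.5)

  m <- ouf_default()
  wins_ouf <- vapply(1:25, function(r) {
    tr <- simulate_track(m, sampling_schedule(256, 8), seed = 7100 + r)
    s <- select_model(tr, c("IID", "OU", "OUF"))
    s$model$kind == "OUF"
  }, TRUE)
  expect_gt(mean(wins_ouf), 0.5)
})

test_that("model selection honors its contract", {
  m <- ouf_default()
  tr <- simulate_track(m, sampling_schedule(64, 4), seed = 77)
  # candidate set of size one returns that fit
  one <- select_model(tr, "OU")
  expect_identical(one$model$kind, "OU")
  # adding a strictly worse candidate never changes the winner
  both <- select_model(tr, c("OU", "OUF"))
  more <- select_model(tr, c("IID", "OU", "OUF"))
  expect_identical(both$model$kind, more$model$kind)
  expect_equal(both$aicc, more$aicc)
})

test_that("AICc reduces to AIC at large n and diverges at tiny n", {
  ll <- -123.4; k <- 5
  expect_equal(aicc(ll, k, 1e5), -2 * ll + 2 * k, tolerance = 1e-3)
  expect_identical(aicc(ll, k, 5), Inf)
})

test_that("parameter-recovery RMSE decreases with effective sample size", {
  m <- movement_model("OU", sigma2 = 1e6, tau_p = 1)
  rmse <- vapply(c(8, 32, 128), function(dur) {
    est <- vapply(1:12, function(r) {
      tr <- simulate_track(m, sampling_schedule(dur, 8), seed = 8000 + r)
      fit_ml(tr, "OU")$model$tau_p
    }, 0)
    sqrt(mean((est - 1)^2))
  }, 0)
  expect_true(all(diff(rmse) < 0))
})

test_that("likelihood input validation catches degenerate tracks", {
  m <- movement_model("OU", sigma2 = 1, tau_p = 1)
  expect_error(model_loglik(m, track(0, matrix(0, 1, 2))), "at least 2")
  expect_error(fit_ml(track(c(0, 1), matrix(0, 2, 2)), "OU"), "at least 3")
})

test_that("fitting with a fixed location-error variance recovers the process", {
  m <- movement_model("OU", mu = c(10, 10), sigma2 = 1e6, tau_p = 1,
                      error_var = 2500)
  tr <- simulate_track(m, sampling_schedule(256, 8), seed = 55)
  f <- fit_ml(tr, "OU", error_var = 2500)
  expect_true(f$convergence)
  expect_equal(f$model$error_var, 2500)
  expect_lt(abs(f$model$tau_p - 1), 0.3)
  expect_lt(abs(f$model$sigma2 / 1e6 - 1), 0.3)
  # the filter likelihood with error still matches the dense oracle
  expect_equal(model_loglik(f$model, tr), dense_loglik(f$model, tr),
               tolerance = 1e-8)
})
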