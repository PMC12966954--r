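# Independent brute-force oracles used across the suite.  These are written
# from the closed-form kernels directly (dense O(n^2)/O(n^3) linear algebra)
# and never touch the package's sequential filter.

# closed-form positional autocovariance written out independently
kernel_acv <- function(model, lag) {
  s2 <- model$sigma2
  switch(model$kind,
    IID = ifelse(lag == 0, s2, 0),
    OU = s2 * exp(-lag / model$tau_p),
    OUF = {
      tp <- model$tau_p; tv <- model$tau_v
      s2 * (tp * exp(-lag / tp) - tv * exp(-lag / tv)) / (tp - tv)
    },
    stop("no stationary kernel for ", model$kind))
}

# dense covariance matrix of the observed positions (stationary kinds),
# including the location-error nugget
dense_cov_stationary <- function(model, times) {
  K <- outer(times, times, function(a, b) kernel_acv(model, abs(a - b)))
  K + diag(rep(model$error_var, length(times)))
}

# dense covariance of positions 2..n conditional on the first position:
# BM: D * min(s, t); IOU: integrated stationary-OU velocity covariance
dense_cov_conditional <- function(model, times) {
  Tq <- times - times[1]
  Ti <- Tq[-1]
  n <- length(Ti)
  if (model$kind == "BM") {
    K <- outer(Ti, Ti, pmin) * model$diffusion
  } else {
    b <- model$tau_v
    sv <- model$diffusion / (2 * b)
    Fab <- function(A, B) {
      lo <- pmin(A, B); hi <- pmax(A, B)
      2 * b * lo - 2 * b^2 * (1 - exp(-lo / b)) +
        b^2 * (1 - exp(-lo / b) - exp((lo - hi) / b) + exp(-hi / b))
    }
    K <- sv * outer(Ti, Ti, Fab)
  }
  K + diag(rep(model$error_var, n)) + model$error_var
}

gauss_ll <- function(K, z) {
  L <- chol(K)
  w <- backsolve(L, z, transpose = TRUE)
  -0.5 * (length(z) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(w^2))
}

# dense joint Gaussian log-likelihood of a track under a model, the O(n^3)
# oracle for the filter: stationary kinds marginal, BM/IOU conditional on
# the first observation
dense_loglik <- function(model, tr) {
  if (model$kind %in% c("BM", "IOU")) {
    K <- dense_cov_conditional(model, tr$times)
    sum(vapply(1:2, function(a)
      gauss_ll(K, tr$coords[-1, a] - tr$coords[1, a]), 0))
  } else {
    K <- dense_cov_stationary(model, tr$times)
    sum(vapply(1:2, function(a)
      gauss_ll(K, tr$coords[, a] - model$mu[a]), 0))
  }
}

# dense Gaussian-process regression oracle for the kriging smoother
# (stationary kinds): conditional mean and per-axis variance at query times
dense_krige <- function(model, tr, qt) {
  K <- dense_cov_stationary(model, tr$times)
  ks <- outer(qt, tr$times, function(a, b) kernel_acv(model, abs(a - b)))
  A <- ks %*% solve(K)
  mx <- model$mu[1] + A %*% (tr$coords[, 1] - model$mu[1])
  my <- model$mu[2] + A %*% (tr$coords[, 2] - model$mu[2])
  v <- kernel_acv(model, 0) - rowSums(A * ks)
  data.frame(t = qt, x = as.numeric(mx), y = as.numeric(my),
             var = pmax(v, 0))
}

# random stationary model generator for property-style loops
random_model <- function(kind, error_var = 0) {
  s2 <- exp(runif(1, 0, 4))
  tp <- exp(runif(1, -1, 2))
  switch(kind,
    IID = movement_model("IID", mu = rnorm(2, 0, 3), sigma2 = s2,
                         error_var = error_var),
    OU = movement_model("OU", mu = rnorm(2, 0, 3), sigma2 = s2, tau_p = tp,
                        error_var = error_var),
    OUF = movement_model("OUF", mu = rnorm(2, 0, 3), sigma2 = s2,
                         tau_p = tp, tau_v = tp * runif(1, 0.05, 0.8),
                         error_var = error_var),
    BM = movement_model("BM", diffusion = exp(runif(1, 0, 3)),
                        error_var = error_var),
    IOU = movement_model("IOU", diffusion = exp(runif(1, 0, 3)),
                         tau_v = exp(runif(1, -2, 0.5)),
                         error_var = error_var))
}

ouf_default <- function(sigma2 = 1e6, tau_p = 1, tau_v = 0.1, ...) {
  movement_model("OUF", sigma2 = sigma2, tau_p = tau_p, tau_v = tau_v, ...)
}
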