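# Build the per-step transition arrays consumed by the compiled filter.
# Regular schedules have one unique dt, so the d x d blocks are computed once
# per unique step and expanded by index.
transition_seq <- function(model, times) {
  d <- state_dim(model$kind)
  n <- length(times)
  Phis <- numeric(d * d * n)
  Qs <- numeric(d * d * n)
  if (n > 1L) {
    dts <- diff(times)
    uts <- unique(dts)
    tq <- lapply(uts, function(dt) transition(model, dt))
    ti <- match(dts, uts)
    dd <- d * d
    Pm <- vapply(tq, function(b) as.numeric(b$Phi), numeric(dd))
    Qm <- vapply(tq, function(b) as.numeric(b$Q), numeric(dd))
    if (dd == 1L) {
      Phis[2:n] <- Pm[ti]
      Qs[2:n] <- Qm[ti]
    } else {
      Phis[-seq_len(dd)] <- Pm[, ti]
      Qs[-seq_len(dd)] <- Qm[, ti]
    }
  }
  list(Phis = Phis, Qs = Qs, d = d)
}

kalman_init <- function(model) {
  if (model$kind %in% c("BM", "IOU")) {
    d <- state_dim(model$kind)
    P0 <- matrix(0, d, d)
    if (model$kind == "IOU")
      P0[2, 2] <- model$diffusion / (2 * model$tau_v)
    list(P0 = P0, diffuse = TRUE)
  } else {
    list(P0 = stationary_state_cov(model), diffuse = FALSE)
  }
}

# Run the filter (and optionally the fixed-interval smoother) for all
# observation series in Z at once.  Z rows with any NA are treated as
# unobserved query times.
kalman_run <- function(model, times, Z, smooth = FALSE) {
  ts <- transition_seq(model, times)
  init <- kalman_init(model)
  obs <- rowSums(is.na(Z)) == 0L
  kalman_cpp(Z, obs, ts$Phis, ts$Qs, model$error_var, init$P0,
             init$diffuse, smooth, ts$d)
}

#' Exact log-likelihood of a track under a movement model
#'
#' The joint Gaussian log-density of the observed coordinates under the model
#' (including its location-error variance), computed in O(n) by sequential
#' prediction with the state-space filter and summed over the two independent
#' axes. It equals the dense multivariate-Gaussian log-density built from the
#' full covariance kernel. For the diffusive kinds (`BM`/`IOU`) the density is
#' conditional on the first observation (diffuse position prior, stationary
#' velocity prior for `IOU`), so the first location contributes no terms.
#'
#' @param model a [movement_model()].
#' @param x a [track()]; at least 2 locations for autocorrelated kinds.
#' @return scalar log-likelihood.
#' @export
model_loglik <- function(model, x) {
  stopifnot(inherits(model, "movement_model"), inherits(x, "track"))
  n <- n_locations(x)
  if (n >= 2L && any(diff(x$times) == 0)) stop("duplicate timestamps")
  if (!all(is.finite(x$coords))) stop("non-finite coordinates")
  if (n < 2L && model$kind != "IID")
    stop("autocorrelated kinds need at least 2 locations")
  center <- if (model$kind %in% c("BM", "IOU")) c(0, 0) else model$mu
  Z <- sweep(x$coords, 2L, center)
  kf <- kalman_run(model, x$times, Z)
  ok <- !is.na(kf$E[, 1])
  S <- kf$S[ok]
  E <- kf$E[ok, , drop = FALSE]
  -0.5 * sum(2 * log(2 * pi * S) + (E[, 1]^2 + E[, 2]^2) / S)
}

# Innovations of the observed coordinates and of a constant-ones series under
# `model` with zero mean: by linearity of the filter, the innovations at mean
# mu are E[, axis] - mu[axis] * E[, ones], which is how the GLS mean profile
# and the GLS covariance estimate are computed without dense matrices.
innovations_with_ones <- function(model, x) {
  Z <- cbind(x$coords, 1)
  kf <- kalman_run(model, x$times, Z)
  ok <- !is.na(kf$E[, 1])
  list(E = kf$E[ok, , drop = FALSE], S = kf$S[ok])
}

# GLS-profiled mean and the resulting centered innovations
profile_mean <- function(model, x) {
  io <- innovations_with_ones(model, x)
  w <- io$E[, 3] / io$S
  denom <- sum(io$E[, 3] * w)
  mu <- c(sum(io$E[, 1] * w), sum(io$E[, 2] * w)) / denom
  Ec <- cbind(io$E[, 1] - mu[1] * io$E[, 3], io$E[, 2] - mu[2] * io$E[, 3])
  list(mu = mu, E = Ec, S = io$S, mu_var_unit = 1 / denom)
}
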