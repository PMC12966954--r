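#' Small-sample corrected AIC
#'
#' `AICc = -2 loglik + 2 k n / (n - k - 1)` with `n` the nominal number of
#' locations; reduces to AIC as `n` grows and is infinite when `n <= k + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n nominal sample size (locations).
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * loglik + 2 * k * n / (n - k - 1)
}

param_count <- function(kind) {
  # mean (2) + variance (1) [+ tau_p] [+ tau_v] for stationary kinds;
  # the diffusive kinds are conditioned on the first location, so no mean
  switch(kind, IID = 3L, OU = 4L, OUF = 5L, BM = 1L, IOU = 2L)
}

#' Effective sample size of a fitted track
#'
#' The approximate number of home-range crossings in the data: sampling
#' duration divided by the positional autocorrelation timescale for `OU`/`OUF`
#' fits, the nominal sample size for `IID` (independent locations), and `NA`
#' for the non-resident diffusive kinds.
#'
#' @param model a [movement_model()].
#' @param duration sampling duration (days).
#' @param n nominal number of locations.
#' @return effective sample size (range crossings).
#' @export
effective_sample_size <- function(model, duration, n) {
  switch(model$kind,
    IID = as.numeric(n),
    OU = , OUF = duration / model$tau_p,
    NA_real_)
}

#' Effective sampling rate of a fitted track
#'
#' Fixes per range crossing: the positional timescale divided by the median
#' sampling interval.
#'
#' @param fitted a `fitted_model`.
#' @param x the [track()] it was fitted to.
#' @return fixes per range crossing, or `NA` for kinds without `tau_p`.
#' @export
effective_sampling_rate <- function(fitted, x) {
  m <- fitted$model
  if (is.null(m$tau_p)) return(NA_real_)
  m$tau_p / median(diff(x$times))
}

new_fitted_model <- function(model, loglik, n, duration, se = NULL,
                             convergence = TRUE) {
  k <- param_count(model$kind)
  structure(list(model = model, loglik = loglik, k = k, n = n,
                 aicc = aicc(loglik, k, n),
                 n_eff = effective_sample_size(model, duration, n),
                 se = se, convergence = convergence),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model> kind:", x$model$kind, "\n")
  cat("  loglik:", format(x$loglik, digits = 8), " AICc:",
      format(x$aicc, digits = 8), " k:", x$k, " n:", x$n, "\n")
  if (!is.na(x$n_eff)) cat("  effective sample size:",
                           format(x$n_eff, digits = 5), "range crossings\n")
  est <- x$model[c("sigma2", "diffusion", "tau_p", "tau_v")]
  est <- est[!vapply(est, is.null, TRUE)]
  for (nm in names(est)) {
    line <- paste0("  ", nm, ": ", format(est[[nm]], digits = 6))
    if (!is.null(x$se) && nm %in% names(x$se) && is.finite(x$se[[nm]]))
      line <- paste0(line, " (se ", format(x$se[[nm]], digits = 4), ")")
    cat(line, "\n")
  }
  if (!x$convergence) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

# negative log-likelihood with the GLS mean profiled out and, when
# `error_var == 0`, the overall variance scale (sigma2 or diffusion) profiled
# analytically: with R = 0 every innovation variance is proportional to the
# scale, so its ML value is the mean normalized squared innovation.
negll_profiled <- function(kind, x, tau_p = NULL, tau_v = NULL) {
  model <- switch(kind,
    OU = movement_model("OU", sigma2 = 1, tau_p = tau_p),
    OUF = movement_model("OUF", sigma2 = 1, tau_p = tau_p, tau_v = tau_v),
    BM = movement_model("BM", diffusion = 1),
    IOU = movement_model("IOU", diffusion = 1, tau_v = tau_v),
    IID = movement_model("IID", sigma2 = 1))
  if (kind %in% c("BM", "IOU")) {
    kf <- kalman_run(model, x$times, x$coords)
    ok <- !is.na(kf$E[, 1])
    E <- kf$E[ok, , drop = FALSE]; S <- kf$S[ok]
    mu <- c(0, 0)
  } else {
    pm <- profile_mean(model, x)
    E <- pm$E; S <- pm$S; mu <- pm$mu
  }
  cnt <- 2L * nrow(E)
  scale_hat <- sum((E[, 1]^2 + E[, 2]^2) / S) / cnt
  scale_hat <- max(scale_hat, 1e-300)
  nll <- 0.5 * (cnt * log(2 * pi * scale_hat) + 2 * sum(log(S)) + cnt)
  list(nll = nll, scale = scale_hat, mu = mu, loglik = -nll)
}

# negative log-likelihood at explicit parameters (mean profiled for the
# stationary kinds); used both for error_var > 0 fitting and for the
# numerical Hessian behind the reported standard errors
negll_explicit <- function(kind, x, pars, error_var) {
  model <- switch(kind,
    IID = movement_model("IID", sigma2 = pars[["sigma2"]],
                         error_var = error_var),
    OU = movement_model("OU", sigma2 = pars[["sigma2"]],
                        tau_p = pars[["tau_p"]], error_var = error_var),
    OUF = movement_model("OUF", sigma2 = pars[["sigma2"]],
                         tau_p = pars[["tau_p"]], tau_v = pars[["tau_v"]],
                         error_var = error_var),
    BM = movement_model("BM", diffusion = pars[["diffusion"]],
                        error_var = error_var),
    IOU = movement_model("IOU", diffusion = pars[["diffusion"]],
                         tau_v = pars[["tau_v"]], error_var = error_var))
  if (kind %in% c("BM", "IOU")) {
    kf <- kalman_run(model, x$times, x$coords)
    ok <- !is.na(kf$E[, 1])
    E <- kf$E[ok, , drop = FALSE]; S <- kf$S[ok]
    mu <- c(0, 0)
  } else {
    pm <- profile_mean(model, x)
    E <- pm$E; S <- pm$S; mu <- pm$mu
  }
  nll <- 0.5 * sum(2 * log(2 * pi * S) + (E[, 1]^2 + E[, 2]^2) / S)
  list(nll = nll, mu = mu, model = model)
}

natural_params <- function(kind, model) {
  switch(kind,
    IID = c(sigma2 = model$sigma2),
    OU = c(sigma2 = model$sigma2, tau_p = model$tau_p),
    OUF = c(sigma2 = model$sigma2, tau_p = model$tau_p, tau_v = model$tau_v),
    BM = c(diffusion = model$diffusion),
    IOU = c(diffusion = model$diffusion, tau_v = model$tau_v))
}

fit_se <- function(kind, x, model, error_var) {
  pars <- natural_params(kind, model)
  f <- function(logp) {
    p <- exp(logp); names(p) <- names(pars)
    if (kind == "OUF" && p[["tau_v"]] >= p[["tau_p"]]) return(1e12)
    out <- try(negll_explicit(kind, x, as.list(p), error_var)$nll,
               silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e12 else out
  }
  H <- try(optimHess(log(pars), f), silent = TRUE)
  se <- rep(NA_real_, length(pars)); names(se) <- names(pars)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error")) {
      dv <- diag(V)
      good <- is.finite(dv) & dv > 0
      se[good] <- pars[good] * sqrt(dv[good])   # delta method from log scale
    }
  }
  se
}

# timescale search grid and bounds shared by the ML drivers
tau_bounds <- function(x) {
  mdt <- median(diff(x$times))
  dur <- track_duration(x)
  c(lo = 1e-3 * mdt, hi = 10 * dur, mdt = mdt, dur = dur)
}

fit_ou_like <- function(kind, x) {
  # one-dimensional profiled likelihood in the log timescale (tau_p for OU,
  # tau_v for IOU): coarse log-spaced scan, then Brent refinement around the
  # best grid point
  b <- tau_bounds(x)
  grid <- exp(seq(log(b[["lo"]]), log(b[["hi"]]), length.out = 17))
  f <- function(lt) {
    tau <- exp(lt)
    out <- try(if (kind == "OU") negll_profiled("OU", x, tau_p = tau)$nll
               else negll_profiled("IOU", x, tau_v = tau)$nll, silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e12 else out
  }
  vals <- vapply(log(grid), f, 0)
  i <- which.min(vals)
  lo <- log(grid[max(1, i - 1)]); hi <- log(grid[min(length(grid), i + 1)])
  opt <- optim(log(grid[i]), f, method = "Brent", lower = lo, upper = hi)
  list(tau = exp(opt$par), value = opt$value,
       convergence = opt$convergence == 0 && opt$value < 1e11)
}

fit_ouf_profiled <- function(x, n_starts = 5) {
  # two-dimensional search in (log tau_p, logit tau_v/tau_p); the ratio
  # parameterization keeps tau_p > tau_v by construction
  b <- tau_bounds(x)
  f <- function(th) {
    tp <- exp(th[1]); ratio <- stats::plogis(th[2])
    if (tp < b[["lo"]] || tp > b[["hi"]]) return(1e12)
    tv <- ratio * tp
    if (tv <= 0 || tv >= tp) return(1e12)
    out <- try(negll_profiled("OUF", x, tau_p = tp, tau_v = tv)$nll,
               silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e12 else out
  }
  tp_starts <- exp(seq(log(b[["mdt"]]), log(b[["dur"]]),
                       length.out = n_starts))
  starts <- lapply(tp_starts, function(tp) c(log(tp), stats::qlogis(0.2)))
  starts <- c(starts, list(c(log(tp_starts[ceiling(n_starts / 2)]),
                             stats::qlogis(0.02))))
  best <- NULL
  for (s in starts) {
    opt <- optim(s, f, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  tp <- exp(best$par[1]); tv <- stats::plogis(best$par[2]) * tp
  list(tau_p = tp, tau_v = tv, value = best$value,
       convergence = best$convergence == 0 && best$value < 1e11)
}

fit_ml_error0 <- function(x, kind) {
  n <- n_locations(x); dur <- track_duration(x)
  conv <- TRUE
  if (kind == "IID") {
    mu <- colMeans(x$coords)
    s2 <- sum(sweep(x$coords, 2L, mu)^2) / (2 * n)
    model <- movement_model("IID", mu = mu, sigma2 = max(s2, 1e-300))
    ll <- model_loglik(model, x)
  } else if (kind == "BM") {
    pr <- negll_profiled("BM", x)
    model <- movement_model("BM", diffusion = pr$scale)
    ll <- pr$loglik - 0  # scale folded in; recompute for exactness below
    ll <- model_loglik(model, x)
  } else if (kind == "OU") {
    opt <- fit_ou_like("OU", x)
    conv <- opt$convergence
    pr <- negll_profiled("OU", x, tau_p = opt$tau)
    model <- movement_model("OU", mu = pr$mu, sigma2 = pr$scale,
                            tau_p = opt$tau)
    ll <- -pr$nll
  } else if (kind == "IOU") {
    opt <- fit_ou_like("IOU", x)
    conv <- opt$convergence
    pr <- negll_profiled("IOU", x, tau_v = opt$tau)
    model <- movement_model("IOU", diffusion = pr$scale, tau_v = opt$tau)
    ll <- -pr$nll
  } else {
    opt <- fit_ouf_profiled(x)
    conv <- opt$convergence
    pr <- negll_profiled("OUF", x, tau_p = opt$tau_p, tau_v = opt$tau_v)
    model <- movement_model("OUF", mu = pr$mu, sigma2 = pr$scale,
                            tau_p = opt$tau_p, tau_v = opt$tau_v)
    ll <- -pr$nll
  }
  list(model = model, loglik = ll, convergence = conv)
}

fit_ml_error <- function(x, kind, error_var) {
  # with a fixed positive error variance the scale no longer profiles out;
  # optimize all log parameters jointly (mean still profiled)
  n <- n_locations(x)
  b <- tau_bounds(x)
  mu0 <- colMeans(x$coords)
  s2_0 <- max(sum(sweep(x$coords, 2L, mu0)^2) / (2 * n) - error_var,
              1e-6 * error_var + 1e-12)
  make_pars <- function(kind, p) {
    switch(kind,
      IID = list(sigma2 = p[1]),
      OU = list(sigma2 = p[1], tau_p = p[2]),
      OUF = list(sigma2 = p[1], tau_p = p[2], tau_v = p[3] * p[2]),
      BM = list(diffusion = p[1]),
      IOU = list(diffusion = p[1], tau_v = p[2]))
  }
  trans <- function(th, kind) {
    switch(kind,
      OUF = c(exp(th[1]), exp(th[2]), stats::plogis(th[3])),
      exp(th))
  }
  f <- function(th) {
    p <- trans(th, kind)
    pars <- make_pars(kind, p)
    if (!is.null(pars$tau_p) && (pars$tau_p < b[["lo"]] || pars$tau_p > b[["hi"]]))
      return(1e12)
    out <- try(negll_explicit(kind, x, pars, error_var)$nll, silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e12 else out
  }
  D0 <- 2 * s2_0 / b[["mdt"]]
  tp_starts <- exp(seq(log(b[["mdt"]]), log(b[["dur"]]), length.out = 3))
  starts <- switch(kind,
    IID = list(log(s2_0)),
    BM = list(log(D0)),
    OU = lapply(tp_starts, function(tp) c(log(s2_0), log(tp))),
    IOU = lapply(tp_starts, function(tv) c(log(D0), log(tv))),
    OUF = lapply(tp_starts, function(tp)
      c(log(s2_0), log(tp), stats::qlogis(0.2))))
  best <- NULL
  for (s in starts) {
    opt <- if (length(s) == 1L)
      optim(s, f, method = "Brent", lower = s - 12, upper = s + 12)
    else optim(s, f, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  p <- trans(best$par, kind)
  pars <- make_pars(kind, p)
  fin <- negll_explicit(kind, x, pars, error_var)
  model <- fin$model
  model$mu <- fin$mu
  list(model = model, loglik = -fin$nll,
       convergence = best$convergence == 0 && best$value < 1e11)
}

#' Fit a movement model by maximum likelihood
#'
#' Maximizes the exact state-space likelihood over the log-parameterized
#' variance/diffusion and timescales, with the mean location profiled out by
#' generalized least squares at every evaluation and multiple starts across a
#' timescale grid spanning the median sampling interval to the duration
#' (bounds `[1e-3 * median dt, 10 * duration]`). Returns the fit with its
#' AICc and effective sample size; non-convergence is flagged on the result
#' and warned about, never silent.
#'
#' @param x a [track()] with at least 3 locations.
#' @param kind process kind to fit.
#' @param error_var fixed (known) location-error variance per axis (m^2);
#'   not estimated.
#' @param se compute standard errors from the numerical Hessian of the
#'   negative log-likelihood at the optimum (delta method from log scale).
#' @return a `fitted_model`: the ML [movement_model()] plus `loglik`, `k`,
#'   `aicc`, `n`, `n_eff`, `se` and `convergence`.
#' @export
fit_ml <- function(x, kind = "OUF", error_var = 0, se = FALSE) {
  stopifnot(inherits(x, "track"))
  kind <- match.arg(kind, PROCESS_KINDS)
  n <- n_locations(x)
  if (n < 3L) stop("need at least 3 locations to fit")
  fit <- if (error_var == 0) fit_ml_error0(x, kind)
         else fit_ml_error(x, kind, error_var)
  fit$model$error_var <- error_var
  ses <- if (se) fit_se(kind, x, fit$model, error_var) else NULL
  if (!fit$convergence)
    warning("fit_ml(", kind, "): optimizer did not converge; result flagged")
  new_fitted_model(fit$model, fit$loglik, n, track_duration(x), se = ses,
                   convergence = fit$convergence)
}

#' Fit candidate movement models and select by AICc
#'
#' Fits each candidate kind by [fit_ml()] and returns the fit with the lowest
#' AICc; ties are broken toward fewer parameters, then by the fixed kind
#' order IID, BM, OU, IOU, OUF.
#'
#' @param x a [track()].
#' @param kinds character vector of candidate kinds.
#' @param error_var fixed location-error variance (m^2).
#' @return the winning `fitted_model`, with the per-kind AICc table attached
#'   as attribute `"candidates"`.
#' @export
select_model <- function(x, kinds = c("IID", "OU", "OUF"), error_var = 0) {
  stopifnot(length(kinds) >= 1L)
  kinds <- match.arg(kinds, PROCESS_KINDS, several.ok = TRUE)
  fits <- list(); errs <- character()
  for (k in kinds) {
    f <- try(fit_ml(x, k, error_var = error_var), silent = TRUE)
    if (inherits(f, "try-error")) errs[k] <- conditionMessage(attr(f, "condition"))
    else fits[[k]] <- f
  }
  if (length(fits) == 0L)
    stop("all candidate fits failed:\n",
         paste(names(errs), errs, sep = ": ", collapse = "\n"))
  tab <- data.frame(kind = names(fits),
                    aicc = vapply(fits, function(f) f$aicc, 0),
                    k = vapply(fits, function(f) f$k, 0L),
                    loglik = vapply(fits, function(f) f$loglik, 0))
  ord <- order(tab$aicc, tab$k, match(tab$kind, PROCESS_KINDS))
  best <- fits[[tab$kind[ord[1]]]]
  attr(best, "candidates") <- tab[ord, ]
  best
}
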