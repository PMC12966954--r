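#' @useDynLib rvo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qchisq optim optimize optimHess rnorm var sd dnorm pnorm
#'   complete.cases coef lm median qnorm
#' @importFrom utils read.csv write.csv head tail
NULL

PROCESS_KINDS <- c("IID", "BM", "OU", "IOU", "OUF")

# Capability taxonomy of the five process families: which feature positional
# autocorrelation, which feature velocity autocorrelation, and which are
# range-resident (finite long-run coverage areas).
KIND_FLAGS <- data.frame(
  kind = PROCESS_KINDS,
  position_autocorrelated = c(FALSE, TRUE, TRUE, TRUE, TRUE),
  velocity_autocorrelated = c(FALSE, FALSE, FALSE, TRUE, TRUE),
  range_resident = c(TRUE, FALSE, TRUE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Capability flags of a movement-process kind
#'
#' Each continuous-time movement process is characterized by three properties:
#' whether positions are autocorrelated, whether velocities are autocorrelated,
#' and whether the process is range-resident (its coverage areas converge to a
#' finite extent, visible as an asymptote of the semivariance function).
#'
#' @param kind one of `"IID"`, `"BM"`, `"OU"`, `"IOU"`, `"OUF"`.
#' @return a one-row data frame with logical columns
#'   `position_autocorrelated`, `velocity_autocorrelated`, `range_resident`.
#' @export
process_flags <- function(kind) {
  kind <- match.arg(kind, PROCESS_KINDS)
  KIND_FLAGS[KIND_FLAGS$kind == kind, , drop = FALSE]
}

is_stationary_kind <- function(kind) kind %in% c("IID", "OU", "OUF")
is_resident_kind <- function(kind) KIND_FLAGS$range_resident[match(kind, PROCESS_KINDS)]
state_dim <- function(kind) if (kind %in% c("IOU", "OUF")) 2L else 1L

# relative tolerance below which the OUF kernel switches to its tau_p == tau_v
# analytic limit (numerical stability of the 1/(tau_p - tau_v) denominator)
TAU_DEGENERATE_RTOL <- 1e-6

#' Construct a continuous-time movement model
#'
#' A movement model is one of five parametric continuous-time stochastic
#' processes: `IID` (uncorrelated locations), `BM` (Brownian motion), `OU`
#' (Ornstein-Uhlenbeck: position-autocorrelated, range-resident), `IOU`
#' (integrated OU: autocorrelated velocities, endlessly diffusing) and `OUF`
#' (OU foraging: autocorrelated positions and velocities, range-resident).
#' The two coordinate axes are modeled as independent with shared parameters.
#'
#' `BM` is the infinite-`tau_p` limit of `OU`, and `IOU` the infinite-`tau_p`
#' limit of `OUF`; passing `tau_p = Inf` coerces the kind accordingly, in which
#' case `diffusion` must be supplied directly.
#'
#' @param kind process kind, one of `"IID"`, `"BM"`, `"OU"`, `"IOU"`, `"OUF"`.
#' @param mu mean (home-range center) location, length-2 numeric, meters.
#'   Unused by the diffusive kinds `BM`/`IOU`.
#' @param sigma2 stationary per-axis variance (m^2); required for
#'   `IID`/`OU`/`OUF`.
#' @param diffusion increment-variance rate `D` (m^2/day); required for
#'   `BM`/`IOU`.
#' @param tau_p positional autocorrelation timescale (days); `OU`/`OUF`.
#' @param tau_v velocity autocorrelation timescale (days); `IOU`/`OUF`.
#'   For `OUF`, `tau_p > tau_v > 0` is required.
#' @param error_var uncorrelated per-axis location-error variance (m^2, >= 0).
#' @return an object of class `movement_model`.
#' @examples
#' movement_model("OUF", sigma2 = 1e6, tau_p = 1, tau_v = 0.1)
#' movement_model("OU", tau_p = Inf, diffusion = 5e4)  # coerced to BM
#' @export
movement_model <- function(kind, mu = c(0, 0), sigma2 = NULL, diffusion = NULL,
                           tau_p = NULL, tau_v = NULL, error_var = 0) {
  kind <- match.arg(kind, PROCESS_KINDS)
  stopifnot(length(mu) == 2L, is.finite(mu))
  if (!is.null(tau_p) && is.infinite(tau_p)) {
    # Table-1 limits: OU -> BM, OUF -> IOU.  The stationary variance diverges
    # in this limit, so the caller must supply the finite diffusion rate.
    if (is.null(diffusion))
      stop("infinite tau_p: supply `diffusion` directly (BM/IOU limit)")
    kind <- switch(kind, OU = "BM", OUF = "IOU", BM = "BM", IOU = "IOU",
                   stop("infinite tau_p is meaningless for kind IID"))
    tau_p <- NULL
    sigma2 <- NULL
  }
  if (kind %in% c("IID", "OU", "OUF")) {
    if (is.null(sigma2) || !is.finite(sigma2) || sigma2 <= 0)
      stop("kind ", kind, " requires sigma2 > 0")
  }
  if (kind %in% c("BM", "IOU")) {
    if (is.null(diffusion) || !is.finite(diffusion) || diffusion <= 0)
      stop("kind ", kind, " requires diffusion > 0")
  }
  if (kind %in% c("OU", "OUF")) {
    if (is.null(tau_p) || !is.finite(tau_p) || tau_p <= 0)
      stop("kind ", kind, " requires tau_p > 0")
  }
  if (kind %in% c("IOU", "OUF")) {
    if (is.null(tau_v) || !is.finite(tau_v) || tau_v <= 0)
      stop("kind ", kind, " requires tau_v > 0")
  }
  if (kind == "OUF" && tau_v >= tau_p)
    stop("OUF requires tau_p > tau_v")
  if (!is.numeric(error_var) || length(error_var) != 1L || error_var < 0)
    stop("error_var must be a single value >= 0")
  structure(list(kind = kind, mu = as.numeric(mu), sigma2 = sigma2,
                 diffusion = diffusion, tau_p = tau_p, tau_v = tau_v,
                 error_var = error_var),
            class = "movement_model")
}

#' @export
print.movement_model <- function(x, ...) {
  cat("<movement_model> kind:", x$kind, "\n")
  cat("  mu: (", format(x$mu[1]), ",", format(x$mu[2]), ") m\n")
  if (!is.null(x$sigma2)) cat("  sigma2:", format(x$sigma2), "m^2 per axis\n")
  if (!is.null(x$diffusion)) cat("  diffusion:", format(x$diffusion), "m^2/day\n")
  if (!is.null(x$tau_p)) cat("  tau_p:", format(x$tau_p), "days\n")
  if (!is.null(x$tau_v)) cat("  tau_v:", format(x$tau_v), "days\n")
  if (x$error_var > 0) cat("  error_var:", format(x$error_var), "m^2\n")
  invisible(x)
}

tau_degenerate <- function(tau_p, tau_v) {
  abs(tau_p - tau_v) < TAU_DEGENERATE_RTOL * tau_p
}

#' Stationary positional autocovariance
#'
#' Autocovariance of position at a given time lag, per axis. Only the
#' stationary kinds (`IID`, `OU`, `OUF`) possess one; the diffusive kinds
#' (`BM`, `IOU`) have unbounded variance and are described by
#' [semivariance()] instead.
#'
#' Kernels: `IID` is `sigma2` at lag 0 and 0 elsewhere; `OU` is
#' `sigma2 * exp(-lag/tau_p)`; `OUF` is
#' `sigma2 * (tau_p*exp(-lag/tau_p) - tau_v*exp(-lag/tau_v)) / (tau_p - tau_v)`,
#' switching to the analytic limit `sigma2 * (1 + lag/tau) * exp(-lag/tau)`
#' when the two timescales are numerically indistinguishable.
#'
#' @param model a [movement_model()] of stationary kind.
#' @param lag time lag(s), days, `>= 0`; vectorized.
#' @return autocovariance (m^2), same length as `lag`.
#' @export
autocovariance <- function(model, lag) {
  stopifnot(inherits(model, "movement_model"))
  if (any(lag < 0)) stop("lag must be >= 0")
  if (!is_stationary_kind(model$kind))
    stop("kind ", model$kind, " has no stationary autocovariance; ",
         "use semivariance() for diffusive processes")
  s2 <- model$sigma2
  switch(model$kind,
    IID = ifelse(lag == 0, s2, 0),
    OU = s2 * exp(-lag / model$tau_p),
    OUF = {
      tp <- model$tau_p; tv <- model$tau_v
      if (tau_degenerate(tp, tv)) {
        s2 * (1 + lag / tp) * exp(-lag / tp)
      } else {
        s2 * (tp * exp(-lag / tp) - tv * exp(-lag / tv)) / (tp - tv)
      }
    })
}

#' Semivariance function
#'
#' Half the expected squared per-axis displacement between positions a given
#' lag apart, in the convention where stationary kinds satisfy
#' `semivariance(lag) = autocovariance(0) - autocovariance(lag)` (asymptote
#' `sigma2`), while the diffusive kinds grow without bound:
#' `BM` is `diffusion * lag` and `IOU` is
#' `diffusion * (lag - tau_v * (1 - exp(-lag/tau_v)))`.
#'
#' @inheritParams autocovariance
#' @return semivariance (m^2), same length as `lag`.
#' @export
semivariance <- function(model, lag) {
  stopifnot(inherits(model, "movement_model"))
  if (any(lag < 0)) stop("lag must be >= 0")
  switch(model$kind,
    BM = model$diffusion * lag,
    IOU = {
      tv <- model$tau_v
      model$diffusion * (lag - tv * (1 - exp(-lag / tv)))
    },
    autocovariance(model, 0) - autocovariance(model, lag))
}

# OUF companion matrix A = [[0, 1], [-1/(tp*tv), -(1/tp + 1/tv)]] has
# eigenvalues -1/tp and -1/tv; its exponential is computed spectrally, with a
# repeated-eigenvalue branch for the degenerate case.
ouf_expAt <- function(tp, tv, dt) {
  a <- 1 / tp; b <- 1 / tv
  A <- matrix(c(0, -a * b, 1, -(a + b)), 2, 2)
  if (tau_degenerate(tp, tv)) {
    ea <- exp(-a * dt)
    ea * (diag(2) + dt * (A + a * diag(2)))
  } else {
    Pa <- (A + b * diag(2)) / (b - a)
    Pb <- (A + a * diag(2)) / (a - b)
    exp(-a * dt) * Pa + exp(-b * dt) * Pb
  }
}

# stationary state covariance, per axis: Var(x) = sigma2, Cov(x, v) = 0,
# Var(v) = sigma2 / (tau_p * tau_v) for OUF; D / (2 tau_v) for IOU velocity
stationary_state_cov <- function(model) {
  switch(model$kind,
    IID = matrix(model$sigma2),
    OU = matrix(model$sigma2),
    OUF = diag(c(model$sigma2, model$sigma2 / (model$tau_p * model$tau_v))),
    BM = matrix(NA_real_),   # diffuse position
    IOU = diag(c(NA_real_, model$diffusion / (2 * model$tau_v))))
}

#' Exact discrete-time transition law
#'
#' Conditional law of the per-axis state after a time step `dt`: the state is
#' position for `IID`/`BM`/`OU` and (position, velocity) for `IOU`/`OUF`,
#' centered on the mean. Returns the state matrix `Phi` and state-noise
#' covariance `Q` such that `state(t+dt) | state(t) ~ N(Phi state(t), Q)`.
#'
#' `OU`: `Phi = exp(-dt/tau_p)`, `Q = sigma2*(1 - exp(-2dt/tau_p))`.
#' `BM`: `Phi = 1`, `Q = diffusion*dt`. `OUF`: `Phi = expm(dt*A)` with `A` the
#' companion matrix of eigenvalues `-1/tau_p`, `-1/tau_v`, and `Q` from the
#' discrete Lyapunov relation `Q = S - Phi S Phi'` with `S` the stationary
#' state covariance. `IOU`: closed-form integrated-OU transition.
#'
#' @param model a [movement_model()].
#' @param dt time step, days, `> 0`.
#' @return list with components `Phi` (d x d) and `Q` (d x d), d = 1 or 2.
#' @export
transition <- function(model, dt) {
  stopifnot(inherits(model, "movement_model"))
  if (dt <= 0) stop("dt must be > 0")
  switch(model$kind,
    IID = list(Phi = matrix(0), Q = matrix(model$sigma2)),
    OU = {
      phi <- exp(-dt / model$tau_p)
      list(Phi = matrix(phi), Q = matrix(model$sigma2 * (1 - phi^2)))
    },
    BM = list(Phi = matrix(1), Q = matrix(model$diffusion * dt)),
    OUF = {
      Phi <- ouf_expAt(model$tau_p, model$tau_v, dt)
      S <- stationary_state_cov(model)
      Q <- S - Phi %*% S %*% t(Phi)
      Q <- (Q + t(Q)) / 2
      list(Phi = Phi, Q = Q)
    },
    IOU = {
      b <- model$tau_v; D <- model$diffusion
      sv <- D / (2 * b)                      # stationary velocity variance
      eb <- exp(-dt / b)
      Phi <- matrix(c(1, 0, b * (1 - eb), eb), 2, 2)
      Qvv <- sv * (1 - eb^2)
      Qxv <- sv * b * (1 - eb)^2
      Qxx <- sv * (2 * b * dt - 2 * b^2 * (1 - eb) - b^2 * (1 - eb)^2)
      list(Phi = Phi, Q = matrix(c(Qxx, Qxv, Qxv, Qvv), 2, 2))
    })
}

#' Analytic Gaussian coverage-area geometry
#'
#' Area of the smallest region containing probability mass `q` of a bivariate
#' Gaussian with covariance `cov`: the ellipse of squared Mahalanobis radius
#' equal to the chi-square(2 df) `q`-quantile, with area
#' `pi * qchisq(q, 2) * sqrt(det(cov))` (and `qchisq(q, 2) = -2*log(1 - q)`).
#'
#' @param cov symmetric positive-definite 2x2 covariance (m^2).
#' @param q coverage quantile in (0, 1).
#' @return area in m^2; vectorized over `q`.
#' @examples
#' gaussian_coverage_area(diag(2), 0.95)  # pi * 5.991 = 18.82 m^2
#' @export
gaussian_coverage_area <- function(cov, q) {
  check_spd2(cov)
  if (any(q <= 0 | q >= 1)) stop("q must lie in (0, 1)")
  pi * qchisq(q, df = 2) * sqrt(det(cov))
}

check_spd2 <- function(cov) {
  if (!is.matrix(cov) || !all(dim(cov) == 2L))
    stop("cov must be a 2x2 matrix")
  if (max(abs(cov - t(cov))) > 1e-8 * max(abs(cov), 1e-300))
    stop("cov must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("cov must be positive definite")
  invisible(TRUE)
}

#' Analytic coverage region of a Gaussian range distribution
#'
#' @param center length-2 center (m).
#' @param cov 2x2 SPD covariance (m^2).
#' @param q coverage quantile in (0, 1).
#' @return an object of class `gaussian_region` with fields `center`, `cov`,
#'   `q` and the closed-form ellipse `area` (m^2).
#' @export
gaussian_region <- function(center, cov, q) {
  stopifnot(length(center) == 2L, is.finite(center))
  area <- gaussian_coverage_area(cov, q)
  structure(list(center = as.numeric(center), cov = cov, q = q, area = area),
            class = "gaussian_region")
}

#' @export
print.gaussian_region <- function(x, ...) {
  cat("<gaussian_region> ", 100 * x$q, "% coverage area: ",
      format(x$area, digits = 6), " m^2 (", format(x$area / 1e6, digits = 4),
      " km^2)\n", sep = "")
  cat("  center: (", format(x$center[1]), ",", format(x$center[2]), ") m\n")
  invisible(x)
}
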