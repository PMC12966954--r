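#' Sampling schedule
#'
#' A regular observation schedule: `rate` fixes per day over `duration` days,
#' with optional gap intervals removed. Gap intervals are half-open
#' `[start, end)`: a sample falling exactly on `start` is removed, one exactly
#' on `end` is kept.
#'
#' @param duration total span (days), `> 0`.
#' @param rate sampling rate (fixes/day), `> 0`.
#' @param gaps optional list of `c(start, end)` intervals (days) within
#'   `[0, duration]`.
#' @return an object of class `sampling_schedule`.
#' @export
sampling_schedule <- function(duration, rate, gaps = NULL) {
  if (duration <= 0) stop("duration must be > 0")
  if (rate <= 0) stop("rate must be > 0")
  if (!is.null(gaps)) {
    for (g in gaps) {
      if (length(g) != 2L || g[1] >= g[2] || g[1] < 0 || g[2] > duration)
        stop("each gap must be c(start, end) with 0 <= start < end <= duration")
    }
  }
  structure(list(duration = duration, rate = rate, gaps = gaps),
            class = "sampling_schedule")
}

#' Sample times of a schedule
#'
#' The regular grid `0, 1/rate, 2/rate, ... < duration`, with times inside any
#' half-open gap `[start, end)` removed.
#'
#' @param schedule a [sampling_schedule()].
#' @return strictly increasing numeric vector of times (days).
#' @export
schedule_times <- function(schedule) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  times <- seq(0, schedule$duration - 1e-9, by = 1 / schedule$rate)
  for (g in schedule$gaps) times <- times[times < g[1] | times >= g[2]]
  if (length(times) == 0L) stop("gaps removed every sample time")
  times
}

# PSD matrix square root that tolerates tiny negative eigenvalues from
# cancellation in the Lyapunov noise covariance
psd_sqrt <- function(Q) {
  if (nrow(Q) == 1L) return(matrix(sqrt(max(Q[1, 1], 0))))
  e <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate a movement track
#'
#' Exact draw of a continuous-time movement process at the requested times via
#' the discrete transition recursion: the state is initialized from the
#' stationary law for `IID`/`OU`/`OUF`, or at the supplied `origin` (with the
#' velocity drawn from its stationary law for `IOU`) for the endlessly
#' diffusing kinds. Axes are drawn independently; if `error_var > 0`,
#' i.i.d. Gaussian location error is added per axis. The same
#' `(seed, model, times)` always reproduces the same track.
#'
#' @param model a [movement_model()].
#' @param schedule a [sampling_schedule()], or a numeric vector of strictly
#'   increasing sample times (days).
#' @param seed optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @param origin initial position (length-2, m) — required for `BM`/`IOU`.
#' @param id optional track label.
#' @return a [track()].
#' @export
simulate_track <- function(model, schedule, seed = NULL, origin = NULL,
                           id = NULL) {
  stopifnot(inherits(model, "movement_model"))
  times <- if (inherits(schedule, "sampling_schedule"))
    schedule_times(schedule) else as.numeric(schedule)
  n <- length(times)
  if (n < 1L) stop("no sample times")
  if (n > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  d <- state_dim(model$kind)
  nonstat <- model$kind %in% c("BM", "IOU")
  if (nonstat && is.null(origin))
    stop("kind ", model$kind, " requires an `origin` position")

  # initial state per axis
  state <- matrix(0, d, 2)
  if (nonstat) {
    state[1, ] <- origin
    if (model$kind == "IOU") {
      sv <- model$diffusion / (2 * model$tau_v)
      state[2, ] <- rnorm(2, 0, sqrt(sv))
    }
  } else {
    S0 <- stationary_state_cov(model)
    L0 <- psd_sqrt(S0)
    state <- L0 %*% matrix(rnorm(2 * d), d, 2)
  }

  out <- matrix(0, n, 2)
  out[1, ] <- state[1, ]
  if (n > 1L) {
    dts <- diff(times)
    uts <- unique(dts)
    trans <- lapply(uts, function(dt) {
      tq <- transition(model, dt)
      list(Phi = tq$Phi, L = psd_sqrt(tq$Q))
    })
    ti <- match(dts, uts)
    for (i in 2:n) {
      tr <- trans[[ti[i - 1]]]
      state <- tr$Phi %*% state + tr$L %*% matrix(rnorm(2 * d), d, 2)
      out[i, ] <- state[1, ]
    }
  }
  mu <- if (nonstat) c(0, 0) else model$mu
  out <- sweep(out, 2, -mu)
  if (model$error_var > 0)
    out <- out + matrix(rnorm(2 * n, 0, sqrt(model$error_var)), n, 2)
  track(times, out, id = id)
}
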