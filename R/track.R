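#' Construct a telemetry track
#'
#' A track is a time-ordered set of planar locations: strictly increasing
#' timestamps in days and an n x 2 coordinate matrix in meters.
#'
#' @param times numeric vector of timestamps (days), strictly increasing.
#' @param coords n x 2 numeric matrix of locations (m).
#' @param id optional label for the individual.
#' @return an object of class `track`.
#' @export
track <- function(times, coords, id = NULL) {
  times <- as.numeric(times)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have two columns (x, y)")
  n <- length(times)
  if (n < 1L) stop("track needs at least one location")
  if (nrow(coords) != n) stop("times and coords lengths differ")
  if (!all(is.finite(times)) || !all(is.finite(coords)))
    stop("times and coords must be finite")
  if (n > 1L && any(diff(times) <= 0)) {
    if (any(diff(times) == 0)) stop("duplicate timestamps in track")
    stop("times must be strictly increasing")
  }
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(times = times, coords = coords, id = id), class = "track")
}

#' @export
print.track <- function(x, ...) {
  n <- length(x$times)
  cat("<track>", if (!is.null(x$id)) paste0("'", x$id, "'"), n, "locations,",
      format(diff(range(x$times)), digits = 5), "days\n")
  invisible(x)
}

#' Number of locations in a track
#' @param x a [track()].
#' @return integer location count.
#' @export
n_locations <- function(x) length(x$times)

track_duration <- function(x) diff(range(x$times))

#' Thin a track by index
#'
#' Retains every `keep_every`-th location (indices 1, 1+k, 1+2k, ...),
#' emulating the progressive subsampling of a finely sampled movement track.
#' Thinning by 1 is the identity, and thinning composes:
#' `thin_track(thin_track(x, a), b)` equals `thin_track(x, a*b)`.
#'
#' @param x a [track()].
#' @param keep_every positive integer subsampling factor.
#' @return the thinned [track()].
#' @export
thin_track <- function(x, keep_every) {
  stopifnot(inherits(x, "track"))
  keep_every <- as.integer(keep_every)
  if (keep_every < 1L) stop("keep_every must be >= 1")
  idx <- seq(1L, n_locations(x), by = keep_every)
  track(x$times[idx], x$coords[idx, , drop = FALSE], id = x$id)
}

#' Split a track into past and future halves
#'
#' The extrapolative cross-validation split: the first `ceiling(n/2)`
#' locations form the training half, the remainder the test half.
#'
#' @param x a [track()] with at least 4 locations.
#' @return list with components `train` and `test`, both [track()]s.
#' @export
split_half <- function(x) {
  stopifnot(inherits(x, "track"))
  n <- n_locations(x)
  if (n < 4L) stop("need at least 4 locations to split")
  k <- ceiling(n / 2)
  list(train = track(x$times[1:k], x$coords[1:k, , drop = FALSE], id = x$id),
       test = track(x$times[(k + 1):n], x$coords[(k + 1):n, , drop = FALSE],
                    id = x$id))
}

# mean Earth radius (m) for the local tangent-plane projection
EARTH_RADIUS <- 6371008.8

#' Read a telemetry track from CSV
#'
#' Two dialects are supported. The planar dialect has columns `t` (days),
#' `x`, `y` (meters). The Movebank dialect has columns `timestamp` (ISO-8601,
#' UTC), `location-long`, `location-lat` (decimal degrees) and
#' `individual-local-identifier`; it is projected to meters by a local
#' tangent-plane approximation about the mean location
#' (`x = R cos(lat0) dlon`, `y = R dlat`, `R = 6371008.8 m`), with time in
#' days since the first timestamp. Rows with missing coordinates are dropped
#' with a message; duplicate timestamps are an error. A Movebank file with
#' several individuals returns a named list of tracks.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default), `"planar"` or `"movebank"`.
#' @return a [track()], or a named list of tracks for multi-individual files.
#' @export
read_track <- function(path, dialect = c("auto", "planar", "movebank")) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- names(df)
  if (dialect == "auto") {
    dialect <- if (all(c("t", "x", "y") %in% cols)) "planar"
      else if (all(c("timestamp", "location-long", "location-lat") %in% cols))
        "movebank"
      else stop("unrecognized track dialect: columns ",
                paste(cols, collapse = ", "))
  }
  if (dialect == "planar") {
    if (!all(c("t", "x", "y") %in% cols))
      stop("planar dialect requires columns t, x, y")
    keep <- complete.cases(df[, c("t", "x", "y")])
    if (any(!keep))
      message("dropped ", sum(!keep), " rows with missing coordinates")
    df <- df[keep, , drop = FALSE]
    df <- df[order(df$t), , drop = FALSE]
    if (anyDuplicated(df$t)) stop("duplicate timestamps in ", path)
    return(track(df$t, cbind(df$x, df$y)))
  }
  # Movebank
  need <- c("timestamp", "location-long", "location-lat")
  if (!all(need %in% cols))
    stop("movebank dialect requires columns ", paste(need, collapse = ", "))
  keep <- complete.cases(df[, need])
  if (any(!keep))
    message("dropped ", sum(!keep), " rows with missing coordinates")
  df <- df[keep, , drop = FALSE]
  ids <- if ("individual-local-identifier" %in% cols)
    as.character(df[["individual-local-identifier"]]) else rep("1", nrow(df))
  one <- function(sub, id) {
    tt <- as.POSIXct(sub$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M", "%Y-%m-%d"))
    o <- order(tt)
    sub <- sub[o, , drop = FALSE]; tt <- tt[o]
    if (anyDuplicated(as.numeric(tt))) stop("duplicate timestamps for ", id)
    days <- as.numeric(difftime(tt, tt[1], units = "days"))
    lon <- sub[["location-long"]]; lat <- sub[["location-lat"]]
    lat0 <- mean(lat); lon0 <- mean(lon)
    x <- EARTH_RADIUS * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180
    y <- EARTH_RADIUS * (lat - lat0) * pi / 180
    track(days, cbind(x, y), id = id)
  }
  out <- lapply(split(seq_len(nrow(df)), ids), function(ix)
    one(df[ix, , drop = FALSE], ids[ix[1]]))
  if (length(out) == 1L) out[[1]] else out
}

#' Write a track as planar CSV
#'
#' Writes the `t,x,y` planar dialect (header, UTF-8, `.` decimal) so that
#' `read_track(write_track(x, path))` round-trips.
#'
#' @param x a [track()].
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(x, path) {
  stopifnot(inherits(x, "track"))
  df <- data.frame(t = x$times, x = x$coords[, 1], y = x$coords[, 2])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a movement model as YAML
#'
#' Models serialize as a flat mapping of the [movement_model()] fields.
#'
#' @param path YAML file path.
#' @return for `read_model`, a [movement_model()].
#' @export
read_model <- function(path) {
  m <- yaml::read_yaml(path)
  movement_model(kind = m$kind,
                 mu = if (is.null(m$mu)) c(0, 0) else as.numeric(m$mu),
                 sigma2 = m$sigma2, diffusion = m$diffusion,
                 tau_p = m$tau_p, tau_v = m$tau_v,
                 error_var = if (is.null(m$error_var)) 0 else m$error_var)
}

#' @rdname read_model
#' @param model a [movement_model()].
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "movement_model"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(model)), path)
  invisible(path)
}
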