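#' Construct a location trajectory
#'
#' A trajectory is one user's time-ordered sequence of location visits. It is
#' the unit on which all entropy and overlap estimators operate. Events are
#' sorted by timestamp on construction (stable, so ingestion order breaks
#' ties); consecutive duplicate visits are retained, since the match-length
#' estimators are defined on the raw event sequence.
#'
#' @param user_id Scalar identifier for the user.
#' @param loc Character vector of location identifiers, one per visit.
#' @param time Numeric vector of timestamps (UTC seconds), same length as
#'   `loc`. Any `POSIXct` input is converted.
#' @param lat,lon Optional numeric coordinate vectors (decimal degrees).
#'
#' @return An object of class `trajectory` with fields `user_id`, `loc`,
#'   `time`, optional `lat`/`lon`, the visit count `N`, the distinct-location
#'   count `n`, and the distinct-location set `Y`.
#' @examples
#' tr <- trajectory("u1", c("home", "work", "home"), c(0, 3600, 7200))
#' tr$N; tr$n; tr$Y
#' @export
trajectory <- function(user_id, loc, time, lat = NULL, lon = NULL) {
  stopifnot(length(user_id) == 1L, length(loc) == length(time))
  if (length(loc) == 0L) stop("a trajectory needs at least one event (N >= 1)")
  loc <- as.character(loc)
  if (anyNA(loc) || any(!nzchar(loc))) stop("location ids must be non-empty")
  time <- as.numeric(time)
  if (anyNA(time) || any(!is.finite(time))) stop("timestamps must be finite")
  if (!is.null(lat)) {
    stopifnot(length(lat) == length(loc), length(lon) == length(loc))
    ok <- is.na(lat) | (lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180)
    if (!all(ok, na.rm = TRUE)) stop("coordinates out of range")
  }
  ord <- order(time)
  out <- list(
    user_id = as.character(user_id),
    loc = loc[ord],
    time = time[ord],
    lat = if (!is.null(lat)) as.numeric(lat)[ord],
    lon = if (!is.null(lon)) as.numeric(lon)[ord],
    N = length(loc),
    n = length(unique(loc)),
    Y = unique(loc)
  )
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  span <- diff(range(x$time)) / 86400
  cat(sprintf("<trajectory> user %s: N = %d visits, n = %d distinct locations, %.1f days\n",
              x$user_id, x$N, x$n, span))
  invisible(x)
}

# integer-code two location vectors over their joint alphabet
encode_locs <- function(a, b = NULL) {
  f <- factor(c(a, b))
  codes <- as.integer(f)
  list(a = codes[seq_along(a)],
       b = if (!is.null(b)) codes[length(a) + seq_along(b)])
}

as_trajectory <- function(x) {
  if (inherits(x, "trajectory")) return(x)
  stop("expected a trajectory object")
}
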