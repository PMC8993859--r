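#' Describe a check-in file dialect
#'
#' Archived LBSN snapshots ship as headerless TSV with columns
#' (user, ISO-8601 check-in time, latitude, longitude, location id). Other
#' layouts are described by reordering `columns` and switching `time_format`.
#'
#' @param columns Character vector naming, in file order, a permutation of
#'   `"user"`, `"time"`, `"lat"`, `"lon"`, `"loc"` (coordinates optional).
#' @param time_format `"iso8601"` or `"epoch"` (numeric seconds).
#' @param sep Field separator.
#' @param tz Timezone applied to ISO timestamps without an offset; the
#'   internal time axis is always UTC seconds.
#' @return A `checkin_dialect` list usable by [read_checkins()].
#' @export
checkin_dialect <- function(columns = c("user", "time", "lat", "lon", "loc"),
                            time_format = c("iso8601", "epoch"),
                            sep = "\t", tz = "UTC") {
  time_format <- match.arg(time_format)
  stopifnot(all(c("user", "time", "loc") %in% columns))
  structure(list(columns = columns, time_format = time_format,
                 sep = sep, tz = tz),
            class = "checkin_dialect")
}

parse_times <- function(x, dialect) {
  if (dialect$time_format == "epoch") return(suppressWarnings(as.numeric(x)))
  x <- sub("Z$", "", x)
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = dialect$tz)
  miss <- is.na(t)
  if (any(miss)) # fall back to a space-separated variant
    t[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%d %H:%M:%S", tz = dialect$tz)
  as.numeric(t)
}

new_checkin_dataset <- function(trajectories, edges = NULL, calls = NULL,
                                provenance = list()) {
  structure(list(trajectories = trajectories, edges = edges, calls = calls,
                 provenance = provenance),
            class = "checkin_dataset")
}

#' @export
print.checkin_dataset <- function(x, ...) {
  nev <- sum(vapply(x$trajectories, function(tr) tr$N, integer(1)))
  cat(sprintf("<checkin_dataset> %d users, %d events", length(x$trajectories), nev))
  if (!is.null(x$edges)) cat(sprintf(", %d social edges", nrow(x$edges)))
  if (!is.null(x$calls)) cat(sprintf(", %d calls", nrow(x$calls)))
  cat("\n")
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, function(p) paste(format(p), collapse = ","),
                                      character(1)),
                               sep = "=", collapse = "; "), "\n")
  invisible(x)
}

events_frame_to_dataset <- function(df, provenance) {
  ord <- order(df$user, df$time) # stable: preserves file order within ties
  df <- df[ord, , drop = FALSE]
  trajectories <- lapply(split(df, df$user), function(d) {
    trajectory(d$user[1], d$loc, d$time,
               lat = if ("lat" %in% names(d)) d$lat,
               lon = if ("lon" %in% names(d)) d$lon)
  })
  new_checkin_dataset(trajectories, provenance = provenance)
}

#' Read a check-in log
#'
#' Reads an LBSN-style check-in file (one event per row), drops rows with
#' missing or unparseable mandatory attributes (user, timestamp, location id),
#' and returns per-user trajectories sorted by timestamp. Rows whose
#' coordinates are present but out of range keep the event with coordinates
#' blanked.
#'
#' @param path Path to the file.
#' @param dialect A [checkin_dialect()].
#' @param report_json Optional path; if given, the ingestion report is also
#'   written there as JSON.
#' @return A `checkin_dataset`; the ingestion report (rows read / dropped,
#'   users found) is stored in its `provenance$ingestion`.
#' @export
read_checkins <- function(path, dialect = checkin_dialect(), report_json = NULL) {
  if (!file.exists(path)) stop("check-in file not found: ", path)
  raw <- utils::read.table(path, sep = dialect$sep, header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", fill = TRUE,
                           col.names = dialect$columns,
                           na.strings = c("", "NA"))
  rows_read <- nrow(raw)
  df <- data.frame(user = raw$user,
                   time = parse_times(raw$time, dialect),
                   loc = raw$loc, stringsAsFactors = FALSE)
  has_coords <- all(c("lat", "lon") %in% dialect$columns)
  if (has_coords) {
    df$lat <- suppressWarnings(as.numeric(raw$lat))
    df$lon <- suppressWarnings(as.numeric(raw$lon))
    bad <- !is.na(df$lat) & !is.na(df$lon) &
      (df$lat < -90 | df$lat > 90 | df$lon < -180 | df$lon > 180)
    df$lat[bad] <- NA_real_
    df$lon[bad] <- NA_real_
  }
  keep <- !is.na(df$user) & nzchar(df$user) & is.finite(df$time) &
    !is.na(df$loc) & nzchar(df$loc)
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no valid check-in rows in ", path)
  report <- list(source = path, rows_read = rows_read, rows_dropped = dropped,
                 users_found = length(unique(df$user)))
  if (!is.null(report_json))
    jsonlite::write_json(report, report_json, auto_unbox = TRUE)
  message(sprintf("read_checkins: %d rows read, %d dropped, %d users",
                  rows_read, dropped, report$users_found))
  events_frame_to_dataset(df, provenance = list(ingestion = report))
}

#' Read a declared social edge list
#'
#' @param path Two-column file of user-id pairs (tab-separated).
#' @return A two-column character matrix of undirected, deduplicated edges
#'   with self-loops removed; the number of skipped malformed rows is in
#'   `attr(, "skipped")`.
#' @export
read_social_edges <- function(path) {
  if (!file.exists(path)) stop("edge file not found: ", path)
  raw <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                    colClasses = "character", quote = "",
                                    comment.char = "", fill = TRUE,
                                    na.strings = c("", "NA")),
                  error = function(e) data.frame())
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    m <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
    attr(m, "skipped") <- if (nrow(raw)) nrow(raw) else 0L
    return(m)
  }
  a <- raw[[1]]; b <- raw[[2]]
  ok <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b)
  skipped <- sum(!ok) + sum(a[ok] == b[ok]) # malformed + self-loops
  a2 <- a[ok]; b2 <- b[ok]
  keep <- a2 != b2
  a2 <- a2[keep]; b2 <- b2[keep]
  lo <- pmin(a2, b2); hi <- pmax(a2, b2)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  m <- cbind(a = lo[!dup], b = hi[!dup])
  if (sum(!ok) > 0) warning(sum(!ok), " malformed edge rows skipped")
  attr(m, "skipped") <- skipped
  m
}

#' Read a call-detail-record log
#'
#' Each valid call yields one check-in event for the caller at the antenna
#' serving the call; the full call log (both directions of reciprocal pairs)
#' is retained for social-tie inference. Calls with a missing antenna are
#' dropped from the event stream but kept in the call log.
#'
#' @param path CSV with columns caller, callee, timestamp (epoch seconds),
#'   antenna_id.
#' @return A `checkin_dataset` whose `calls` field holds the call log.
#' @export
read_cdr <- function(path) {
  if (!file.exists(path)) stop("CDR file not found: ", path)
  raw <- utils::read.table(path, sep = ",", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "", na.strings = c("", "NA"))
  names(raw) <- c("caller", "callee", "time", "antenna")[seq_len(ncol(raw))]
  rows_read <- nrow(raw)
  time <- suppressWarnings(as.numeric(raw$time))
  valid_call <- !is.na(raw$caller) & !is.na(raw$callee) & is.finite(time)
  calls <- data.frame(caller = raw$caller[valid_call],
                      callee = raw$callee[valid_call],
                      time = time[valid_call], stringsAsFactors = FALSE)
  has_antenna <- valid_call & !is.na(raw$antenna) & nzchar(raw$antenna)
  dropped <- sum(!has_antenna)
  df <- data.frame(user = raw$caller[has_antenna],
                   time = time[has_antenna],
                   loc = raw$antenna[has_antenna], stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no valid CDR rows in ", path)
  report <- list(source = path, rows_read = rows_read, rows_dropped = dropped,
                 users_found = length(unique(df$user)))
  message(sprintf("read_cdr: %d rows read, %d dropped as events, %d users",
                  rows_read, dropped, report$users_found))
  ds <- events_frame_to_dataset(df, provenance = list(ingestion = report))
  ds$calls <- calls
  ds
}

#' Attach a social edge list to a dataset
#' @param ds A `checkin_dataset`.
#' @param edges Edge matrix from [read_social_edges()] (or any two-column
#'   character matrix).
#' @return The dataset with `edges` set.
#' @export
set_social_edges <- function(ds, edges) {
  stopifnot(inherits(ds, "checkin_dataset"))
  ds$edges <- edges
  ds
}

#' Filter a dataset to active users
#'
#' Drops users with fewer than `min_checkins` logged events (the threshold is
#' inclusive: a user with exactly `min_checkins` events is retained). Social
#' edges and call-log rows are restricted to retained users, and the filter
#' settings are recorded once in the provenance, so filtering is idempotent.
#'
#' @param ds A `checkin_dataset`.
#' @param min_checkins Minimum event count per user (default 150).
#' @param min_active_days Optional minimum number of distinct UTC days with
#'   activity; `NULL` (default) disables the check.
#' @return The filtered `checkin_dataset`.
#' @export
filter_dataset <- function(ds, min_checkins = 150L, min_active_days = NULL) {
  stopifnot(inherits(ds, "checkin_dataset"))
  keep <- vapply(ds$trajectories, function(tr) {
    ok <- tr$N >= min_checkins
    if (ok && !is.null(min_active_days))
      ok <- length(unique(floor(tr$time / 86400))) >= min_active_days
    ok
  }, logical(1))
  if (!any(keep))
    stop("all users removed by min_checkins = ", min_checkins,
         "; lower the threshold")
  ds$trajectories <- ds$trajectories[keep]
  users <- names(ds$trajectories)
  if (!is.null(ds$edges) && nrow(ds$edges) > 0) {
    e <- ds$edges[ds$edges[, 1] %in% users & ds$edges[, 2] %in% users, ,
                  drop = FALSE]
    attr(e, "skipped") <- attr(ds$edges, "skipped")
    ds$edges <- e
  }
  if (!is.null(ds$calls) && nrow(ds$calls) > 0)
    ds$calls <- ds$calls[ds$calls$caller %in% users & ds$calls$callee %in% users, ,
                         drop = FALSE]
  ds$provenance$min_checkins <- min_checkins
  ds$provenance$min_active_days <- min_active_days
  ds
}

#' Descriptive mobility statistics
#'
#' Jump lengths are great-circle distances between consecutive events of a
#' user; the radius of gyration is the root-mean-square great-circle distance
#' of a user's events from their coordinate centroid. Distances use the
#' haversine formula with Earth radius 6371 km. Users without coordinates are
#' excluded from the distance statistics and flagged.
#'
#' @param ds A `checkin_dataset`.
#' @return A `mobility_summary` with per-user distinct-location counts,
#'   radii of gyration (km), per-user jump-length lists (km), and the ids of
#'   users lacking coordinates.
#' @export
summarize_mobility <- function(ds) {
  stopifnot(inherits(ds, "checkin_dataset"))
  R_km <- 6371
  distinct <- vapply(ds$trajectories, function(tr) tr$n, integer(1))
  no_coords <- character(0)
  jumps <- list(); rgyr <- c()
  for (tr in ds$trajectories) {
    if (is.null(tr$lat) || all(is.na(tr$lat))) {
      no_coords <- c(no_coords, tr$user_id)
      next
    }
    ok <- !is.na(tr$lat) & !is.na(tr$lon)
    p <- cbind(tr$lon[ok], tr$lat[ok])
    if (nrow(p) >= 2) {
      jumps[[tr$user_id]] <- geosphere::distHaversine(p[-nrow(p), , drop = FALSE],
                                                      p[-1, , drop = FALSE],
                                                      r = R_km)
    } else {
      jumps[[tr$user_id]] <- numeric(0)
    }
    centroid <- cbind(mean(p[, 1]), mean(p[, 2]))
    d <- geosphere::distHaversine(p, centroid[rep(1, nrow(p)), , drop = FALSE],
                                  r = R_km)
    rgyr[tr$user_id] <- sqrt(mean(d^2))
  }
  structure(list(distinct_locations = distinct, radius_of_gyration = rgyr,
                 jump_lengths = jumps, users_without_coords = no_coords),
            class = "mobility_summary")
}

#' @export
print.mobility_summary <- function(x, ...) {
  cat(sprintf("<mobility_summary> %d users; median distinct locations %.0f",
              length(x$distinct_locations), median(x$distinct_locations)))
  if (length(x$radius_of_gyration))
    cat(sprintf("; median r_g %.2f km", median(x$radius_of_gyration)))
  cat("\n")
  invisible(x)
}
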