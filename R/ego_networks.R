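#' Time-lag colocation window
#'
#' Two users colocate at lag `T` when they visit the same location with a
#' time separation `|dt|` inside the band `[T - half_width, T]` hours — the
#' alter's event falls in the window `half_width` long ending `T` hours
#' before, or starting `T` hours after, the ego's event. `T = half_width =
#' 1/2` gives the contiguous one-hour window `|dt| <= 1/2 h` used for the
#' main colocation networks.
#'
#' @param T Lag in hours (>= `half_width`).
#' @param half_width Window width in hours (default 1/2).
#' @return A `lag_window` object.
#' @export
lag_window <- function(T = 0.5, half_width = 0.5) {
  stopifnot(T >= half_width, half_width > 0)
  structure(list(T = T, half_width = half_width), class = "lag_window")
}

#' @export
print.lag_window <- function(x, ...) {
  cat(sprintf("<lag_window> |dt| in [%.2f, %.2f] hours\n",
              x$T - x$half_width, x$T))
  invisible(x)
}

# Count colocation event pairs for every ordered user pair: rows of
# (ego, alter, loc, n). Every qualifying (ego event, alter event) pair at
# the same location with (T - half_width) <= |dt| <= T counts one
# colocation, so weights are symmetric by construction. "calendar" mode
# buckets time into aligned bins of 2*half_width hours instead (contiguous
# window only), for robustness checks against the sliding default.
colocation_pair_counts <- function(ds, window = lag_window(),
                                   mode = c("sliding", "calendar")) {
  mode <- match.arg(mode)
  user <- loc <- time <- u1 <- u2 <- t1 <- lo <- hi <- bin <- NULL # data.table NSE
  ev <- data.table::rbindlist(lapply(ds$trajectories, function(tr) {
    data.table::data.table(user = tr$user_id, loc = tr$loc, time = tr$time)
  }))
  if (nrow(ev) == 0L)
    return(data.table::data.table(ego = character(), alter = character(),
                                  loc = character(), n = integer()))
  if (mode == "calendar") {
    if (window$T != window$half_width)
      stop("calendar bucketing is defined only for the contiguous window")
    width <- 2 * window$half_width * 3600
    ev[, bin := floor(time / width)]
    j <- merge(ev[, .(u1 = user, loc, bin)], ev[, .(u2 = user, loc, bin)],
               by = c("loc", "bin"), allow.cartesian = TRUE)
    j <- j[u1 != u2]
  } else {
    hi_s <- window$T * 3600
    lo_s <- (window$T - window$half_width) * 3600
    a <- ev[, .(loc, u1 = user, t1 = time)]
    b <- ev[, .(loc, u2 = user, t2 = time, lo = time - hi_s, hi = time + hi_s)]
    j <- a[b, on = .(loc, t1 >= lo, t1 <= hi), allow.cartesian = TRUE,
           nomatch = NULL,
           .(loc = x.loc, u1 = x.u1, t1 = x.t1, u2 = i.u2, t2 = i.t2)]
    j <- j[u1 != u2 & abs(t1 - t2) >= lo_s & abs(t1 - t2) <= hi_s]
  }
  out <- j[, .(n = .N), by = .(ego = u1, alter = u2, loc)]
  out[]
}

new_ego_network <- function(ego, flavor, lag, alters_df) {
  structure(list(ego = ego, flavor = flavor, lag = lag, alters = alters_df),
            class = "ego_network")
}

#' @export
print.ego_network <- function(x, ...) {
  cat(sprintf("<ego_network> ego %s, flavor %s (lag %.2f h): %d alters (%d retained)\n",
              x$ego, x$flavor, x$lag, nrow(x$alters), sum(x$alters$retained)))
  invisible(x)
}

rank_alters <- function(df) {
  # weights nonincreasing; ties broken lexicographically by alter id
  df <- df[order(-df$weight, df$alter), , drop = FALSE]
  df$rank <- ifelse(df$retained, cumsum(df$retained), NA_integer_)
  rownames(df) <- NULL
  df
}

social_pair_set <- function(ds) {
  keys <- character(0)
  if (!is.null(ds$edges) && nrow(ds$edges) > 0)
    keys <- c(keys, paste(pmin(ds$edges[, 1], ds$edges[, 2]),
                          pmax(ds$edges[, 1], ds$edges[, 2]), sep = "\r"))
  if (!is.null(ds$calls) && nrow(ds$calls) > 0)
    keys <- c(keys, paste(pmin(ds$calls$caller, ds$calls$callee),
                          pmax(ds$calls$caller, ds$calls$callee), sep = "\r"))
  unique(keys)
}

#' Build egocentric social networks
#'
#' Social alters are the ego's declared friends (edge list) or, for CDR
#' data, users exchanging at least `min_reciprocal_calls` reciprocal calls
#' with the ego (counted as `2 * min(calls a->b, calls b->a)`, threshold
#' inclusive). Only alters with logged trajectories are kept. Alters are
#' ranked by their colocation frequency with the ego in the contiguous
#' window, so "top social tie" is well defined; friends who never colocate
#' have weight 0.
#'
#' @param ds A `checkin_dataset` with an edge list and/or call log.
#' @param window A [lag_window()] used for the ranking colocation counts.
#' @param min_reciprocal_calls CDR social-tie threshold (default 30).
#' @return Named list of `ego_network` objects (flavor `"social"`), one per
#'   ego with at least one alter.
#' @export
build_social_networks <- function(ds, window = lag_window(),
                                  min_reciprocal_calls = 30L) {
  stopifnot(inherits(ds, "checkin_dataset"))
  users <- names(ds$trajectories)
  pairs <- list()
  if (!is.null(ds$edges) && nrow(ds$edges) > 0) {
    e <- ds$edges[ds$edges[, 1] %in% users & ds$edges[, 2] %in% users, ,
                  drop = FALSE]
    pairs <- c(pairs, list(data.frame(a = c(e[, 1], e[, 2]),
                                      b = c(e[, 2], e[, 1]),
                                      stringsAsFactors = FALSE)))
  }
  if (length(pairs) == 0L && !is.null(ds$calls) && nrow(ds$calls) > 0) {
    cl <- ds$calls[ds$calls$caller %in% users & ds$calls$callee %in% users, ]
    key <- paste(cl$caller, cl$callee, sep = "\r")
    cnt <- table(key)
    dirs <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
    d <- data.frame(a = dirs[, 1], b = dirs[, 2], k = as.integer(cnt),
                    stringsAsFactors = FALSE)
    rev_k <- d$k[match(paste(d$b, d$a, sep = "\r"), paste(d$a, d$b, sep = "\r"))]
    rev_k[is.na(rev_k)] <- 0L
    rec <- 2L * pmin(d$k, rev_k)
    d <- d[rec >= min_reciprocal_calls, c("a", "b")]
    pairs <- c(pairs, list(d))
  }
  if (length(pairs) == 0L)
    stop("dataset has neither a social edge list nor a call log")
  tie <- unique(do.call(rbind, pairs))
  cp <- colocation_pair_counts(ds, window)
  wtab <- if (nrow(cp)) {
    stats::aggregate(n ~ ego + alter, data = as.data.frame(cp), FUN = sum)
  } else data.frame(ego = character(), alter = character(), n = integer())
  wkey <- paste(wtab$ego, wtab$alter, sep = "\r")
  out <- list()
  for (ego in sort(unique(tie$a))) {
    alters <- sort(unique(tie$b[tie$a == ego]))
    if (length(alters) == 0L) next
    w <- wtab$n[match(paste(ego, alters, sep = "\r"), wkey)]
    w[is.na(w)] <- 0L
    df <- rank_alters(data.frame(alter = alters, weight = as.numeric(w),
                                 retained = TRUE, stringsAsFactors = FALSE))
    out[[ego]] <- new_ego_network(ego, "social", window$T, df)
  }
  out
}

#' Build egocentric (lagged) colocation networks
#'
#' A tie links an ego and another user whenever they check in at the same
#' location within the lag window; the tie weight is the total number of
#' such event pairs and alters are ranked by weight. Pairs that are declared
#' social ties (edge list) or that exchanged any call (CDR) are excluded,
#' making the colocation alters non-social by construction.
#'
#' @param ds A `checkin_dataset`.
#' @param window A [lag_window()]; the default `T = 1/2` gives the
#'   contiguous one-hour window.
#' @param mode `"sliding"` (default) or `"calendar"` bucketing.
#' @param drop_top_location_colocators Optional stand-in filter for spurious
#'   colocators: when `TRUE`, removes alters whose colocations with the ego
#'   all occur at the ego's single most-visited location (default off).
#' @return Named list of `ego_network` objects (flavor `"colocation"` or
#'   `"lagged-colocation"`); users with no colocators simply have no entry.
#' @export
build_colocation_networks <- function(ds, window = lag_window(),
                                      mode = c("sliding", "calendar"),
                                      drop_top_location_colocators = FALSE) {
  stopifnot(inherits(ds, "checkin_dataset"))
  mode <- match.arg(mode)
  cp <- as.data.frame(colocation_pair_counts(ds, window, mode))
  social <- social_pair_set(ds)
  if (nrow(cp)) {
    pk <- paste(pmin(cp$ego, cp$alter), pmax(cp$ego, cp$alter), sep = "\r")
    cp <- cp[!(pk %in% social), , drop = FALSE]
  }
  flavor <- if (window$T == window$half_width) "colocation" else "lagged-colocation"
  out <- list()
  if (nrow(cp) == 0L) return(out)
  for (ego in sort(unique(cp$ego))) {
    sub <- cp[cp$ego == ego, , drop = FALSE]
    if (drop_top_location_colocators) {
      tr <- ds$trajectories[[ego]]
      top_loc <- names(sort(table(tr$loc), decreasing = TRUE))[1]
      only_top <- tapply(sub$loc, sub$alter, function(l) all(l == top_loc))
      sub <- sub[!only_top[sub$alter], , drop = FALSE]
      if (nrow(sub) == 0L) next
    }
    w <- tapply(sub$n, sub$alter, sum)
    df <- rank_alters(data.frame(alter = names(w), weight = as.numeric(w),
                                 retained = TRUE, stringsAsFactors = FALSE))
    out[[ego]] <- new_ego_network(ego, flavor, window$T, df)
  }
  out
}

#' Drop alters that carry no better-than-random information
#'
#' Retains only alters whose cross-entropy about the ego is strictly below
#' \eqn{\log_2 n_A}, i.e. whose cross-predictability exceeds the
#' random-guessing bound \eqn{1/n_A}. Ranks are recomputed among survivors
#' (in the original weight order); removed alters keep a row with
#' `retained = FALSE`.
#'
#' @param net An `ego_network`.
#' @param ds The `checkin_dataset` holding the ego's and alters'
#'   trajectories.
#' @return The filtered `ego_network`.
#' @export
filter_better_than_random <- function(net, ds) {
  stopifnot(inherits(net, "ego_network"), inherits(ds, "checkin_dataset"))
  ego <- ds$trajectories[[net$ego]]
  if (is.null(ego)) stop("no trajectory for ego ", net$ego)
  bound <- log2(ego$n)
  keep <- vapply(net$alters$alter, function(aid) {
    B <- ds$trajectories[[aid]]
    if (is.null(B) || B$N < 2) return(FALSE)
    cross_entropy(ego, B)$value < bound
  }, logical(1))
  net$alters$retained <- net$alters$retained & keep
  net$alters <- rank_alters(net$alters)
  net
}

#' Egos eligible in both network flavors
#'
#' @param social,coloc Named lists of `ego_network`s (e.g. from
#'   [build_social_networks()] and [build_colocation_networks()]).
#' @param min_alters Minimum retained alters required in each flavor
#'   (default 10, inclusive).
#' @return Character vector of eligible ego ids (warning when empty).
#' @export
select_eligible_egos <- function(social, coloc, min_alters = 10L) {
  n_ret <- function(nets) vapply(nets, function(x) sum(x$alters$retained), integer(1))
  s <- n_ret(social); k <- n_ret(coloc)
  egos <- intersect(names(s)[s >= min_alters], names(k)[k >= min_alters])
  if (length(egos) == 0L) warning("no egos eligible in both networks")
  sort(egos)
}

#' Egos eligible at every temporal lag
#'
#' @param networks Named list, one entry per lag, each a named list of
#'   `ego_network`s.
#' @param min_alters Minimum retained alters per lag.
#' @return Character vector: the intersection of eligible ego sets over all
#'   lags (warning when empty, which does occur on sparse data).
#' @export
common_egos_across_lags <- function(networks, min_alters = 10L) {
  sets <- lapply(networks, function(nets) {
    n_ret <- vapply(nets, function(x) sum(x$alters$retained), integer(1))
    names(n_ret)[n_ret >= min_alters]
  })
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) warning("no egos are eligible at every lag")
  sort(common)
}

#' Flatten ego networks to an edge table
#'
#' @param nets Named list of `ego_network`s.
#' @return A data.frame with columns ego, alter, flavor, lag_hours, weight,
#'   rank, retained (suitable for CSV export).
#' @export
network_edges_df <- function(nets) {
  rows <- lapply(nets, function(x) {
    if (nrow(x$alters) == 0L) return(NULL)
    data.frame(ego = x$ego, alter = x$alters$alter, flavor = x$flavor,
               lag_hours = x$lag, weight = x$alters$weight,
               rank = x$alters$rank, retained = x$alters$retained,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
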