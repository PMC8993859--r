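# In-code fixtures shared across the suite.

# a trajectory from parallel location/time vectors
tr <- function(user, loc, time = seq_along(loc), ...) {
  trajectory(user, loc, time, ...)
}

# a checkin_dataset from a list of user -> list(loc=, time=[, lat=, lon=])
make_ds <- function(users, edges = NULL, calls = NULL) {
  trajs <- lapply(names(users), function(u) {
    x <- users[[u]]
    trajectory(u, x$loc,
               if (is.null(x$time)) seq_along(x$loc) else x$time,
               lat = x$lat, lon = x$lon)
  })
  names(trajs) <- names(users)
  ds <- mobflow:::new_checkin_dataset(trajs, provenance = list(source = "test"))
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    colnames(edges) <- c("a", "b")
    ds$edges <- edges
  }
  ds$calls <- calls
  ds
}

# write a headerless LBSN-style TSV check-in file, return its path
write_checkin_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(rows, path)
  path
}

# all restricted growth strings of a given length with at most max_sym blocks:
# the canonical representatives of sequences under bijective relabeling
rgs_matrix <- function(len, max_sym = 4L) {
  M <- matrix(1L, 1, 1)
  mx <- 1L
  while (ncol(M) < len) {
    k <- pmin(mx + 1L, max_sym)
    rows <- rep(seq_len(nrow(M)), k)
    vals <- sequence(k)
    mx <- pmax(mx[rows], vals)
    M <- cbind(M[rows, , drop = FALSE], vals)
  }
  M
}
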